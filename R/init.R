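#' Stripe layout of the model tissue
#'
#' Describes how the rows of the initial lattice tile into the medial
#' "outside" stripe, the inner-hair-cell row, the single pillar-cell row,
#' the lateral-inhibition (OHC) zone, and the lateral "outside" stripe.
#' Row indices are 0-based from the bottom (medial edge) of the lattice.
#'
#' @param rows,cols lattice dimensions (cells); `rows` must be even for
#'   periodic tiling.
#' @param side hexagon side length (the length unit of the model).
#' @param outside_bottom,ihc_rows,pillar_rows,ohc_rows,outside_top number
#'   of cell rows per stripe, bottom to top; must sum to `rows` and the
#'   pillar stripe must be a single row.
#' @return a `corti_region_spec` list.
#' @export
region_spec <- function(rows = 12, cols = 12, side = 1,
                        outside_bottom = 2, ihc_rows = 1, pillar_rows = 1,
                        ohc_rows = 5, outside_top = 3) {
  if (pillar_rows != 1L) abort_cfg("pillar stripe must be one cell row",
                                   "pillar_rows")
  tot <- outside_bottom + ihc_rows + pillar_rows + ohc_rows + outside_top
  if (tot != rows)
    abort_cfg(sprintf("stripes cover %d rows but lattice has %d", tot, rows),
              "rows")
  if (rows < 4 || cols < 4) abort_cfg("lattice must be at least 4 x 4")
  if (rows %% 2 != 0) abort_cfg("rows must be even for periodic tiling",
                                "rows")
  structure(list(rows = rows, cols = cols, side = side,
                 outside_bottom = outside_bottom, ihc_rows = ihc_rows,
                 pillar_rows = pillar_rows, ohc_rows = ohc_rows,
                 outside_top = outside_top),
            class = "corti_region_spec")
}

# Row stripe label for each 0-based row index.
stripe_of_row <- function(spec, row) {
  b1 <- spec$outside_bottom
  b2 <- b1 + spec$ihc_rows
  b3 <- b2 + spec$pillar_rows
  b4 <- b3 + spec$ohc_rows
  ifelse(row < b1, "outside",
         ifelse(row < b2, "ihc",
                ifelse(row < b3, "pillar",
                       ifelse(row < b4, "ohc", "outside_top"))))
}

#' Regular hexagonal lattice on the torus
#'
#' Builds a rows x cols tiling of regular (pointy-top) hexagons with
#' doubly periodic boundaries. Every vertex is 3-valent; on the torus
#' V = 2F and E = 3F, so the Euler relation V - E + F = 0 holds.
#'
#' @param spec a [region_spec()].
#' @return a `corti_tissue` with all cells of class `outside` (classes are
#'   assigned by [assign_regions()]); the attribute `"lattice_row"` keeps
#'   each cell's construction row.
#' @export
hexagonal_lattice <- function(spec = region_spec()) {
  R <- spec$rows; C <- spec$cols; s <- spec$side
  Lx <- C * sqrt(3) * s
  Ly <- R * 1.5 * s
  ang <- pi / 6 + (0:5) * pi / 3         # ccw, pointy-top
  vx_off <- s * cos(ang); vy_off <- s * sin(ang)
  n_cells <- R * C
  cell_row <- rep(0:(R - 1), each = C)
  cell_col <- rep(0:(C - 1), times = R)
  cx <- (cell_col + 0.5 * (cell_row %% 2)) * sqrt(3) * s
  cy <- cell_row * 1.5 * s
  allx <- wrap_coord(rep(cx, each = 6) + rep(vx_off, n_cells), Lx)
  ally <- wrap_coord(rep(cy, each = 6) + rep(vy_off, n_cells), Ly)
  # exact dedup via integer lattice coordinates (x in sqrt(3)/2 units,
  # y in 1/2 units), wrapped on the torus
  ix_off <- c(1L, 0L, -1L, -1L, 0L, 1L)
  iy_off <- c(1L, 2L, 1L, -1L, -2L, -1L)
  ix <- (rep(2L * cell_col + cell_row %% 2L, each = 6) +
           rep(ix_off, n_cells)) %% (2L * C)
  iy <- (rep(3L * cell_row, each = 6) + rep(iy_off, n_cells)) %% (3L * R)
  key <- ix + 2L * C * iy
  ukey <- unique(key)
  vid <- match(key, ukey)
  first <- !duplicated(key)
  # rows of pos indexed by vertex id (unique keys appear in vid order)
  pos <- cbind(allx[first], ally[first])
  cells <- split(vid, rep(seq_len(n_cells), each = 6))
  state <- new_tissue(pos, cells, rep("outside", n_cells),
                      domain = c(Lx, Ly), y0 = 0)
  attr(state, "lattice_row") <- cell_row
  attr(state, "region_spec") <- spec
  cnt <- tissue_counts(state)
  if (cnt["vertices"] != 2L * n_cells || cnt["junctions"] != 3L * n_cells)
    abort_cfg("lattice dimensions incompatible with periodic tiling")
  state
}

#' Disorder a lattice by randomized tensions and preferred areas
#'
#' Relaxation dynamics with per-junction tension multipliers and per-cell
#' preferred-area multipliers re-drawn uniformly every few steps, turning
#' the degenerate hexagonal packing into a disordered polygonal mosaic
#' with a spread of areas and neighbor numbers.
#'
#' @param state a `corti_tissue` (usually a fresh lattice).
#' @param params a `corti_params`.
#' @param n_cycles number of randomization cycles.
#' @param steps_per_cycle relaxation steps per cycle.
#' @param range multiplicative range for the uniform draws.
#' @return the disordered `corti_tissue` (multipliers reset to 1 on exit).
#' @export
disorder_lattice <- function(state, params, n_cycles = 10,
                             steps_per_cycle = 20, range = c(0.5, 1.5)) {
  if (n_cycles == 0) return(state)
  for (cyc in seq_len(n_cycles)) {
    state$edge_gamma_scale <- stats::runif(length(state$edge_gamma_scale),
                                           range[1], range[2])
    state$A0_scale[] <- stats::runif(length(state$A0_scale),
                                     range[1], range[2])
    for (i in seq_len(steps_per_cycle)) {
      state <- step_tissue(state, params)
      ts <- topology_step(state, params)
      state <- ts$state
    }
  }
  state$edge_gamma_scale[] <- 1
  state$A0_scale[] <- 1
  state
}

#' Assign region classes by centroid stripe
#'
#' Labels each cell by the stripe its centroid falls in: `outside`
#' (medial), `IHC` row (alternating `IHC`/`SC` cells), the single `pillar`
#' row, the OHC zone (class `SC` until lateral inhibition differentiates
#' hair cells), and lateral `outside`. Sets `state$y0` to the
#' pillar-row/OHC interface so that external forces are measured from it.
#' High tension on pillar/non-pillar junctions comes from the tension
#' table (`"pillar:*"`), which straightens the row under relaxation.
#'
#' @param state a `corti_tissue`.
#' @param spec a [region_spec()].
#' @return the labeled `corti_tissue`.
#' @export
assign_regions <- function(state, spec = attr(state, "region_spec")) {
  g <- tissue_geometry(state)
  ids <- which(state$alive)
  yc <- wrap_coord(g$centroid[ids, 2], state$domain[[2]])
  rowh <- 1.5 * spec$side
  row <- floor((yc + rowh / 2) / rowh) %% spec$rows
  stripe <- stripe_of_row(spec, row)
  cls <- rep("outside", length(ids))
  cls[stripe == "pillar"] <- "pillar"
  cls[stripe == "ohc"] <- "SC"
  # IHC row: alternating inner hair cells, mechanically present but
  # excluded from all statistics
  ihc_ids <- ids[stripe == "ihc"]
  if (length(ihc_ids)) {
    xo <- order(wrap_coord(g$centroid[ihc_ids, 1], state$domain[[1]]))
    cls[match(ihc_ids[xo], ids)] <-
      rep_len(c("IHC", "SC"), length(ihc_ids))
    # SCs between IHCs belong to the medial region, not the OHC zone:
    # mark them outside so they never differentiate
    cls[match(ihc_ids[xo], ids)][rep_len(c(FALSE, TRUE),
                                         length(ihc_ids))] <- "outside"
  }
  state$class[ids] <- cls
  b3 <- spec$outside_bottom + spec$ihc_rows + spec$pillar_rows
  state$y0 <- (b3 - 0.5) * rowh  # top edge of the pillar row stripe
  state
}

#' Lateral-inhibition patterning of the OHC zone
#'
#' Random sequential adsorption of hair-cell fate: repeatedly pick a
#' random zone cell and let it differentiate only if it has no hair-cell
#' neighbor, until no further cell can differentiate (or `hc_cap` is
#' reached). The result is a maximal independent set on the zone
#' adjacency graph when uncapped: no two hair cells touch, and every
#' remaining supporting cell touches at least one hair cell.
#'
#' @param state a `corti_tissue` with the OHC zone labeled (class `SC`).
#' @param hc_cap maximum number of hair cells allowed to differentiate.
#' @return the patterned `corti_tissue`.
#' @export
lateral_inhibition <- function(state, hc_cap = Inf) {
  repeat {
    if (sum(state$class == "HC" & state$alive) >= hc_cap) break
    ok <- which(state$alive & state$class == "SC" &
                  !touches_class(state, "HC"))
    if (!length(ok)) break
    pick <- if (length(ok) == 1) ok else sample(ok, 1)
    state$class[pick] <- "HC"
  }
  state
}

#' Ongoing differentiation rule
#'
#' Called every simulation step: if a supporting cell in the OHC zone has
#' no hair-cell neighbor and the hair-cell count is below `hc_cap`, one
#' such cell (chosen at random) differentiates.
#'
#' @inheritParams lateral_inhibition
#' @return list with the updated `state` and `converted` (cell id or
#'   `NULL`).
#' @export
maybe_differentiate <- function(state, hc_cap) {
  if (sum(state$class == "HC" & state$alive) >= hc_cap)
    return(list(state = state, converted = NULL))
  ok <- which(state$alive & state$class == "SC" &
                !touches_class(state, "HC"))
  if (!length(ok)) return(list(state = state, converted = NULL))
  pick <- if (length(ok) == 1) ok else sample(ok, 1)
  state$class[pick] <- "HC"
  list(state = state, converted = pick)
}

#' Label the top border of the OHC region
#'
#' At the end of the compaction stage the `outside` cells in contact with
#' the OHC region (hair or supporting cells) are relabeled
#' `top_boundary`; statistics exclude hair cells touching them, and the
#' refinement stage raises the tension of their OHC-facing junctions.
#'
#' @param state a `corti_tissue`.
#' @return the relabeled `corti_tissue`.
#' @export
label_top_boundary <- function(state) {
  touch <- touches_class(state, c("HC", "SC"))
  sel <- state$alive & state$class == "outside" & touch
  g <- tissue_geometry(state)
  # only the lateral side: cells above the pillar interface
  yrel <- min_image(g$centroid[, 2] - state$y0, state$domain[[2]])
  sel <- sel & yrel > 0
  state$class[sel] <- "top_boundary"
  state
}

#' Build the standard initial condition
#'
#' Hexagonal lattice, disordering, region assignment, relaxation of the
#' pillar boundary, and lateral-inhibition patterning of the OHC zone —
#' the state from which the staged protocols start.
#'
#' @param spec a [region_spec()].
#' @param params a `corti_params`.
#' @param seed integer seed (all randomness in the initializer).
#' @param disorder_cycles randomization cycles for [disorder_lattice()].
#' @param hc_cap hair-cell cap: the number of hair cells that fits
#'   exactly three rows on the periodic strip. At the default mechanics
#'   a row holds about `2 * cols / 3` alternating hair cells, so the
#'   default cap is `2 * cols`.
#' @param relax_steps relaxation steps after region assignment (straightens
#'   the pillar boundary before patterning).
#' @return a patterned `corti_tissue` ready for [run_stage1()].
#' @export
init_tissue <- function(spec = region_spec(), params = model_params(),
                        seed = NULL, disorder_cycles = 10,
                        hc_cap = 2 * spec$cols, relax_steps = 100) {
  if (!is.null(seed)) set.seed(seed)
  state <- hexagonal_lattice(spec)
  dis_params <- model_params(sigma = 0, eta = 0, zeta = 0, f_noise = 0,
                             epsilon = params$epsilon)
  state <- disorder_lattice(state, dis_params, n_cycles = disorder_cycles)
  state <- assign_regions(state, spec)
  # relax with the boundary unpinned so the high pillar tension can pull
  # the pillar/OHC interface straight; later stages pin it
  relax_params <- params
  relax_params$eta <- 0; relax_params$zeta <- 0; relax_params$sigma <- 0
  relax_params$f_noise <- 0
  relax_params$pin_classes <- character(0)
  for (i in seq_len(relax_steps)) {
    state <- step_tissue(state, relax_params)
    state <- topology_step(state, relax_params)$state
  }
  state <- lateral_inhibition(state, hc_cap = hc_cap)
  attr(state, "hc_cap") <- hc_cap
  state
}
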