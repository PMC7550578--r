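#' Polygonal tissue state
#'
#' The mutable object advanced by the simulator: a doubly periodic (or
#' planar) polygonal mesh in which every cell is a simple polygon stored as
#' a counter-clockwise cycle of vertex ids, every junction is shared by
#' exactly two cells, and each cell carries a class label (`HC`, `SC`,
#' `pillar`, `IHC`, `top_boundary`, `outside`).
#'
#' @param pos numeric matrix (n_vertices x 2) of vertex positions.
#' @param cells list of integer vectors, each a counter-clockwise vertex
#'   cycle; dead cells are `integer(0)`.
#' @param class character vector of cell classes, one per cell.
#' @param domain `c(Lx, Ly)` for a torus, or `NULL` for a planar patch
#'   (test fixtures only).
#' @param y0 y-coordinate of the pillar-row/OHC interface, the origin for
#'   the external shear and compression forces.
#' @return An object of class `corti_tissue`.
#' @export
new_tissue <- function(pos, cells, class, domain = NULL, y0 = 0) {
  stopifnot(is.matrix(pos), ncol(pos) == 2, length(cells) == length(class))
  bad <- setdiff(unique(class), CELL_CLASSES)
  if (length(bad)) abort_cfg("unknown cell class", bad[1])
  state <- structure(list(
    pos = unname(pos),
    cells = unname(lapply(cells, as.integer)),
    class = as.character(class),
    alive = lengths(cells) >= 3L,
    domain = domain,
    y0 = y0,
    step = 0L,
    edge_gamma_scale = NULL,   # aligned with edge table below
    A0_scale = rep(1, length(cells)),
    Gamma_scale = rep(1, length(cells)),
    lockout = NULL             # step index until which T1 is forbidden
  ), class = "corti_tissue")
  rebuild_topology(state)
}

# Rebuild the flattened cycle ("slot") arrays and the undirected edge
# table, carrying per-edge attributes across by vertex-pair key.
rebuild_topology <- function(state) {
  alive_ids <- which(state$alive)
  cyc <- state$cells[alive_ids]
  k <- lengths(cyc)
  if (any(k < 3L)) abort_topology("alive cell with fewer than 3 vertices")
  v <- unlist(cyc, use.names = FALSE)
  cell <- rep.int(alive_ids, k)
  # next vertex within each cycle
  idx <- seq_along(v)
  ends <- cumsum(k)
  starts <- ends - k + 1L
  nxt_idx <- idx + 1L
  nxt_idx[ends] <- starts
  prv_idx <- idx - 1L
  prv_idx[starts] <- ends
  nxt <- v[nxt_idx]

  key <- edge_key(v, nxt)
  ekey <- unique(key)
  eid_of_slot <- match(key, ekey)
  tab <- tabulate(eid_of_slot, nbins = length(ekey))
  if (any(tab > 2L))
    abort_topology("junction shared by more than 2 cells")
  if (any(tab < 2L)) {
    # boundary (single-owner) edges are permitted only on planar patches
    # used as test fixtures; the torus is a closed 2-complex
    if (!is.null(state$domain))
      abort_topology(sprintf(
        "junction not shared by exactly 2 cells (%d offenders)",
        sum(tab != 2L)))
  }
  ord <- order(eid_of_slot)
  first_of <- ord[!duplicated(eid_of_slot[ord])]
  last_of <- rev(ord)[!duplicated(eid_of_slot[rev(ord)])]
  last_of <- last_of[match(eid_of_slot[first_of], eid_of_slot[last_of])]
  s1 <- first_of
  s2 <- last_of  # equals s1 for boundary edges: the cell is its own peer
  if (any(cell[s1] == cell[s2] & tab == 2L))
    abort_topology("junction with both sides owned by the same cell")
  edges <- cbind(v1 = v[s1], v2 = nxt[s1], c1 = cell[s1], c2 = cell[s2])

  # carry per-edge attributes by key
  gs <- rep(1, length(ekey))
  lk <- rep(-Inf, length(ekey))
  old <- attr(state, "edge_keys")
  if (!is.null(old)) {
    m <- match(ekey[], old)
    hit <- !is.na(m)
    if (!is.null(state$edge_gamma_scale))
      gs[hit] <- state$edge_gamma_scale[m[hit]]
    if (!is.null(state$lockout))
      lk[hit] <- state$lockout[m[hit]]
  }
  state$edge_gamma_scale <- gs
  state$lockout <- lk
  attr(state, "edge_keys") <- ekey
  attr(state, "edges") <- edges
  attr(state, "slots") <- list(
    v = v, nxt = nxt, cell = cell, k = k, alive_ids = alive_ids,
    starts = starts, ends = ends, prv_idx = prv_idx, nxt_idx = nxt_idx,
    eid = eid_of_slot, other_cell = {
      oc <- integer(length(v))
      oc[s1] <- cell[s2]; oc[s2] <- cell[s1]
      oc
    })
  state
}

tissue_slots <- function(state) attr(state, "slots")
tissue_edges <- function(state) attr(state, "edges")

#' Number of alive cells, referenced vertices and junctions
#' @param state a `corti_tissue`.
#' @return named integer vector with elements `cells`, `vertices`,
#'   `junctions`.
#' @export
tissue_counts <- function(state) {
  sl <- tissue_slots(state)
  c(cells = length(sl$alive_ids),
    vertices = length(unique(sl$v)),
    junctions = nrow(tissue_edges(state)))
}

# Per-slot minimum-image edge vectors and per-cell unwrapped coordinates.
# Returns slot-level dx, dy, len, ux, uy and cell-level area, perim,
# centroid (n_cells-length vectors indexed by cell id; dead cells NA).
# Thin wrapper over the compiled kernel; tissue_geometry_ref is the pure
# R reference implementation kept for cross-checking.
tissue_geometry <- function(state) {
  sl <- tissue_slots(state)
  dom <- if (is.null(state$domain)) numeric(0) else as.numeric(state$domain)
  g <- vm_geometry_cpp(state$pos, sl$v, sl$nxt, sl$cell, sl$starts, sl$k,
                       sl$alive_ids, length(state$cells), dom)
  kfull <- numeric(length(state$cells))
  kfull[sl$alive_ids] <- sl$k
  g$k <- kfull
  g
}

tissue_geometry_ref <- function(state) {
  sl <- tissue_slots(state)
  p <- state$pos
  Lx <- if (is.null(state$domain)) Inf else state$domain[[1]]
  Ly <- if (is.null(state$domain)) Inf else state$domain[[2]]
  dx <- min_image(p[sl$nxt, 1] - p[sl$v, 1], Lx)
  dy <- min_image(p[sl$nxt, 2] - p[sl$v, 2], Ly)
  len <- sqrt(dx * dx + dy * dy)
  # unwrapped coordinates relative to each cell's first vertex:
  # u_1 = 0, u_{i+1} = u_i + d_i  (cycles are short relative to the box)
  csx <- cumsum(dx); csy <- cumsum(dy)
  idx <- seq_along(dx)
  base_x <- rep.int(csx[sl$starts] - dx[sl$starts], sl$k)
  base_y <- rep.int(csy[sl$starts] - dy[sl$starts], sl$k)
  ux <- c(0, csx)[idx] - base_x  # u_i = cumsum up to previous slot - base
  uy <- c(0, csy)[idx] - base_y
  n_cells <- length(state$cells)
  cross <- ux * dy - uy * dx
  area <- rowsum_full(cross, sl$cell, n_cells) / 2
  perim <- rowsum_full(len, sl$cell, n_cells)
  kfull <- numeric(n_cells); kfull[sl$alive_ids] <- sl$k
  cx <- state$pos[sl$v[sl$starts], 1] + rowsum_full(ux, sl$cell, n_cells)[sl$alive_ids] / sl$k
  cy <- state$pos[sl$v[sl$starts], 2] + rowsum_full(uy, sl$cell, n_cells)[sl$alive_ids] / sl$k
  centroid <- matrix(NA_real_, n_cells, 2)
  centroid[sl$alive_ids, 1] <- cx
  centroid[sl$alive_ids, 2] <- cy
  area[!state$alive] <- NA_real_
  perim[!state$alive] <- NA_real_
  list(dx = dx, dy = dy, len = len, ux = ux, uy = uy,
       area = area, perim = perim, centroid = centroid, k = kfull)
}

#' Area of one cell
#'
#' Signed shoelace area of the cell's vertex cycle, made positive, with
#' periodic images resolved by minimum-image unwrapping around the cycle.
#'
#' @param state a `corti_tissue`.
#' @param cell cell id.
#' @return the cell area (length units squared).
#' @export
cell_area <- function(state, cell) {
  if (!state$alive[cell] || length(state$cells[[cell]]) < 3L)
    abort_topology("degenerate cell: fewer than 3 vertices")
  tissue_geometry(state)$area[cell]
}

#' Cell centroids as a tibble
#'
#' Converts the mesh into the flat per-cell table consumed by the analysis
#' operations: one row per alive cell with its class, centroid, area,
#' perimeter and neighbor count.
#'
#' @param state a `corti_tissue`.
#' @return a tibble with columns `id`, `class`, `x`, `y`, `area`,
#'   `perimeter`, `n_neighbors`.
#' @export
as_centroid_tibble <- function(state) {
  g <- tissue_geometry(state)
  ed <- tissue_edges(state)
  nn <- tabulate(c(ed[, "c1"], ed[, "c2"]), nbins = length(state$cells))
  ids <- which(state$alive)
  ctr <- wrap2(g$centroid[ids, , drop = FALSE], state$domain)
  tibble::tibble(
    id = ids, class = state$class[ids],
    x = ctr[, 1], y = ctr[, 2],
    area = g$area[ids], perimeter = g$perim[ids], n_neighbors = nn[ids])
}

#' @method as_tibble corti_tissue
#' @export
as_tibble.corti_tissue <- function(x, ...) as_centroid_tibble(x)

# Cell-cell adjacency pairs (two-column matrix of cell ids).
cell_adjacency <- function(state) {
  ed <- tissue_edges(state)
  ed[, c("c1", "c2"), drop = FALSE]
}

# For each cell, does it touch a cell of any of the given classes?
touches_class <- function(state, classes) {
  ad <- cell_adjacency(state)
  out <- logical(length(state$cells))
  hit1 <- state$class[ad[, 2]] %in% classes
  hit2 <- state$class[ad[, 1]] %in% classes
  out[unique(ad[hit1, 1])] <- TRUE
  out[unique(ad[hit2, 2])] <- TRUE
  out
}

#' Audit the mesh invariants
#'
#' Checks that every junction is shared by exactly two cells, every alive
#' cell is a simple, positively oriented polygon with positive area, and
#' (on the torus) that the Euler relation V - E + F = 0 holds.
#'
#' @param state a `corti_tissue`.
#' @param check_simple also run the O(k^2) self-intersection test per cell
#'   (used in tests; slower).
#' @return `TRUE` invisibly; errors describe the first violation found.
#' @export
audit_tissue <- function(state, check_simple = FALSE) {
  state <- rebuild_topology(state)  # re-validates the 2-cells-per-junction rule
  g <- tissue_geometry(state)
  a <- g$area[state$alive]
  if (any(!is.finite(a)) || any(a <= 0))
    abort_topology("non-positive cell area")
  if (anyNA(state$pos[unique(tissue_slots(state)$v), ]))
    abort_topology("non-finite vertex position")
  for (i in which(state$alive)) {
    cyc <- state$cells[[i]]
    if (anyDuplicated(cyc)) abort_topology(sprintf("cell %d repeats a vertex", i))
  }
  if (!is.null(state$domain)) {
    cnt <- tissue_counts(state)
    if (cnt["vertices"] - cnt["junctions"] + cnt["cells"] != 0L)
      abort_topology("Euler relation V - E + F = 0 violated")
  }
  if (check_simple) {
    sl <- tissue_slots(state)
    g <- tissue_geometry(state)
    for (ci in seq_along(sl$alive_ids)) {
      rng <- sl$starts[ci]:sl$ends[ci]
      px <- g$ux[rng]; py <- g$uy[rng]
      if (polygon_self_intersects(px, py))
        abort_topology(sprintf("cell %d is self-intersecting",
                               sl$alive_ids[ci]))
    }
  }
  invisible(TRUE)
}

# Brute-force segment intersection test on an unwrapped polygon.
polygon_self_intersects <- function(px, py) {
  k <- length(px)
  if (k < 4) return(FALSE)
  x2 <- c(px[-1], px[1]); y2 <- c(py[-1], py[1])
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      if (j == i || j == i %% k + 1 || i == j %% k + 1) next
      if (segments_cross(px[i], py[i], x2[i], y2[i],
                         px[j], py[j], x2[j], y2[j])) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
  d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
  d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' @export
print.corti_tissue <- function(x, ...) {
  cnt <- tissue_counts(x)
  cat("<corti_tissue> ", cnt["cells"], " cells, ", cnt["vertices"],
      " vertices, ", cnt["junctions"], " junctions",
      if (!is.null(x$domain)) sprintf(" | torus %.3g x %.3g", x$domain[1],
                                      x$domain[2]) else " | planar",
      sprintf(" | step %d\n", x$step), sep = "")
  print(table(x$class[x$alive]))
  invisible(x)
}
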