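#' Junctions eligible for a T1 transition
#'
#' Junctions shorter than `params$l_min`, excluding junctions still inside
#' their post-T1 relaxation lockout window and junctions touching the
#' pillar row (whose straight boundary is a fixed feature of the tissue).
#'
#' @param state a `corti_tissue`.
#' @param params a `corti_params`.
#' @param geom optional precomputed `tissue_geometry(state)`.
#' @return integer vector of edge indices into the state's edge table,
#'   ordered shortest first.
#' @export
find_t1_candidates <- function(state, params, geom = NULL) {
  ed <- tissue_edges(state)
  g <- geom %||% tissue_geometry(state)
  len <- edge_lengths(state, g)
  short <- len < params$l_min
  locked <- state$lockout > state$step
  cand <- which(short & !locked & !pillar_edge(state))
  cand[order(len[cand])]
}

# Edges excluded from rewiring: edges owned by the pillar or IHC rows
# (the boundary itself never flips). Edges merely touching a boundary
# vertex may flip -- that is how cells slide along the pillar row -- but
# apply_t1 separately rejects flips that would let a boundary cell grow
# past its width budget.
pillar_edge <- function(state) {
  ed <- tissue_edges(state)
  frozen_cls <- c("pillar", "IHC")
  state$class[ed[, "c1"]] %in% frozen_cls |
    state$class[ed[, "c2"]] %in% frozen_cls
}

# Boundary-row cells must stay compact: reject surgery outcomes where a
# pillar/IHC cell spans more than ~2 lattice columns or 8 vertices.
boundary_cells_ok <- function(state, cells) {
  sel <- cells[state$class[cells] %in% c("pillar", "IHC")]
  if (!length(sel)) return(TRUE)
  if (any(lengths(state$cells[sel]) > 8L)) return(FALSE)
  g <- tissue_geometry(state)
  sl <- tissue_slots(state)
  for (cell in sel) {
    ci <- match(cell, sl$alive_ids)
    rng <- sl$starts[ci]:sl$ends[ci]
    if (diff(range(g$ux[rng])) > 3.6) return(FALSE)
  }
  TRUE
}

# Undirected edge lengths aligned with the edge table.
edge_lengths <- function(state, geom = NULL) {
  if (is.null(geom)) geom <- tissue_geometry(state)
  sl <- tissue_slots(state)
  len <- numeric(nrow(tissue_edges(state)))
  len[sl$eid] <- geom$len
  len
}

#' Apply a T1 (intercalation) transition
#'
#' The junction collapses to its midpoint and re-extends perpendicular at
#' length `l_new_factor * l_min`; the two cells that shared it lose
#' adjacency and the two flanking cells gain it. Both endpoint vertices
#' must be 3-valent. A lockout stamp forbids another T1 on the junction
#' for `params$lockout` steps.
#'
#' @inheritParams find_t1_candidates
#' @param edge row index into the state's edge table.
#' @return list with elements `state` (updated or unchanged tissue) and
#'   `applied` (logical; `FALSE` when the move was skipped as ineligible
#'   or would have produced an invalid mesh).
#' @export
apply_t1 <- function(state, edge, params) {
  ed <- tissue_edges(state)
  a <- unname(ed[edge, "v1"]); b <- unname(ed[edge, "v2"])
  # orient so that cell c1 contains the directed edge a -> b
  cells_ab <- c(ed[edge, "c1"], ed[edge, "c2"])
  dir_ab <- vapply(cells_ab, function(ci) {
    cyc <- state$cells[[ci]]
    k <- length(cyc)
    pos_a <- match(a, cyc)
    cyc[pos_a %% k + 1L] == b
  }, logical(1))
  c1 <- cells_ab[dir_ab][1]
  c2 <- cells_ab[!dir_ab][1]
  if (is.na(c1) || is.na(c2)) return(list(state = state, applied = FALSE))

  owners_a <- cells_containing(state, a)
  owners_b <- cells_containing(state, b)
  if (length(owners_a) != 3L || length(owners_b) != 3L)
    return(list(state = state, applied = FALSE))  # needs 3-valent endpoints
  da <- setdiff(owners_a, c(c1, c2))
  db <- setdiff(owners_b, c(c1, c2))
  if (length(da) != 1L || length(db) != 1L || da == db)
    return(list(state = state, applied = FALSE))
  if (length(state$cells[[c1]]) < 4L || length(state$cells[[c2]]) < 4L)
    return(list(state = state, applied = FALSE))

  # geometry: collapse to midpoint, re-extend along the left normal
  pa <- state$pos[a, ]; pb <- state$pos[b, ]
  d <- c(min_image(pb[1] - pa[1], (state$domain %||% c(Inf, Inf))[[1]]),
         min_image(pb[2] - pa[2], (state$domain %||% c(Inf, Inf))[[2]]))
  m <- pa + d / 2
  e_hat <- d / sqrt(sum(d^2))
  n_hat <- c(-e_hat[2], e_hat[1])   # left normal: points into c1
  l_new <- params$l_new_factor * params$l_min

  new <- state
  new$pos[a, ] <- m + n_hat * l_new / 2
  new$pos[b, ] <- m - n_hat * l_new / 2
  new$cells[[c1]] <- setdiff(new$cells[[c1]], b)
  new$cells[[c2]] <- setdiff(new$cells[[c2]], a)
  new$cells[[da]] <- insert_before(new$cells[[da]], at = a, value = b)
  new$cells[[db]] <- insert_before(new$cells[[db]], at = b, value = a)
  new <- tryCatch(rebuild_topology(new), error = function(e) NULL)
  if (is.null(new)) return(list(state = state, applied = FALSE))
  if (!cells_valid(new, c(c1, c2, da, db)))
    return(list(state = state, applied = FALSE))
  if (!boundary_cells_ok(new, c(c1, c2, da, db)))
    return(list(state = state, applied = FALSE))
  # stamp lockout on the re-extended junction
  eid <- match(edge_key(a, b), attr(new, "edge_keys"))
  new$lockout[eid] <- new$step + params$lockout
  list(state = new, applied = TRUE,
       cells = c(from = c(c1, c2), to = c(da, db)),
       location = wrap2(matrix(m, 1, 2), state$domain)[1, ])
}

# Validate a set of cells after surgery: positive area and simple.
# Cells whose unwrapped extent exceeds half the periodic box cannot be
# assessed (their minimum-image unwrapping is ill-defined); they are
# tolerated so that rescuing intercalations are never vetoed.
cells_valid <- function(state, cells) {
  g <- tissue_geometry(state)
  sl <- tissue_slots(state)
  for (cell in cells) {
    ci <- match(cell, sl$alive_ids)
    rng <- sl$starts[ci]:sl$ends[ci]
    if (cell_oversized(state, g, rng)) next
    if (!is.finite(g$area[cell]) || g$area[cell] <= 0) return(FALSE)
    if (polygon_self_intersects(g$ux[rng], g$uy[rng])) return(FALSE)
  }
  TRUE
}

cell_oversized <- function(state, g, rng, frac = 0.3) {
  if (is.null(state$domain)) return(FALSE)
  diff(range(g$ux[rng])) > frac * state$domain[[1]] ||
    diff(range(g$uy[rng])) > frac * state$domain[[2]]
}

cells_containing <- function(state, vertex) {
  sl <- tissue_slots(state)
  unique(sl$cell[sl$v == vertex])
}

insert_before <- function(cyc, at, value) {
  i <- match(at, cyc)
  append(cyc, value, after = i - 1L)
}

#' Cells eligible for a T2 (delamination) transition
#'
#' Alive cells with area below `params$A_min` whose class is in
#' `params$t2_classes` (supporting and generic cells by default; hair
#' cells only when `params$hc_t2_allowed` is set).
#'
#' @inheritParams find_t1_candidates
#' @return integer vector of cell ids, smallest area first.
#' @export
find_t2_candidates <- function(state, params, geom = NULL) {
  g <- geom %||% tissue_geometry(state)
  classes <- params$t2_classes
  if (isTRUE(params$hc_t2_allowed)) classes <- c(classes, "HC")
  eligible <- state$alive &
    (state$class %in% classes |
       seq_along(state$cells) %in% params$t2_extra_cells)
  area <- g$area
  # degenerate cells stretched around the torus have lost their apical
  # footprint for all practical purposes: delaminate them
  area[overstretched_ids(state, g, 0.45)] <- 0
  sel <- eligible & area < params$A_min
  cand <- which(sel)
  cand[order(area[cand])]
}

#' Apply a T2 (delamination) transition
#'
#' Removes a triangular cell: its three vertices merge at the centroid,
#' the neighbors' cycles are repaired, and the Euler relation is restored
#' (cell count -1, vertex count -2, junction count -3). Non-triangular
#' cells must first be shrunk to triangles through forced T1s. If removal
#' would leave a neighbor with fewer than 3 vertices, the event is
#' deferred.
#'
#' @inheritParams find_t1_candidates
#' @param cell id of the (triangular) cell to remove.
#' @return list with elements `state` and `applied`, as [apply_t1()].
#' @export
apply_t2 <- function(state, cell, params, force = FALSE) {
  cyc <- state$cells[[cell]]
  if (length(cyc) != 3L && !force)
    return(list(state = state, applied = FALSE, reason = "not a triangle"))
  ad <- cell_adjacency(state)
  nb <- unique(c(ad[ad[, 1] == cell, 2], ad[ad[, 2] == cell, 1]))

  dom <- state$domain %||% c(Inf, Inf)
  v1 <- cyc[1]
  dd <- cbind(min_image(state$pos[cyc, 1] - state$pos[v1, 1], dom[[1]]),
              min_image(state$pos[cyc, 2] - state$pos[v1, 2], dom[[2]]))
  ctr <- state$pos[v1, ] + colMeans(dd)

  new <- state
  new$pos[v1, ] <- wrap2(matrix(ctr, 1, 2), state$domain)[1, ]
  new$alive[cell] <- FALSE
  new$cells[[cell]] <- integer(0)
  gone <- cyc[-1]
  touched <- which(vapply(new$cells, function(cc) any(cc %in% gone),
                          logical(1)))
  for (ci in touched) {
    cc <- new$cells[[ci]]
    cc[cc %in% gone] <- v1
    cc <- cc[c(TRUE, diff(cc) != 0)]           # collapse runs
    if (length(cc) > 1 && cc[1] == cc[length(cc)]) cc <- cc[-length(cc)]
    new$cells[[ci]] <- cc
  }
  if (any(lengths(new$cells[new$alive]) < 3L))
    return(list(state = state, applied = FALSE, reason = "thin neighbor"))
  new <- tryCatch(rebuild_topology(new), error = function(e) NULL)
  if (is.null(new)) return(list(state = state, applied = FALSE))
  alive_nb <- nb[new$alive[nb]]
  if (!force && !cells_valid(new, alive_nb))
    return(list(state = state, applied = FALSE))
  list(state = new, applied = TRUE, cells = cell,
       location = wrap2(matrix(ctr, 1, 2), state$domain)[1, ])
}

# Topological events within one step, applied sequentially (candidates
# re-detected after each rewiring): sub-threshold cells are served first
# (T2, via forced T1s while they have more than 3 sides), then
# sub-threshold junctions (T1), up to `max_events` per step so that
# shear-imposed strain can be relieved as fast as it accumulates.
# Returns list(state, events = list()).
topology_events <- function(state, params, max_events = 8L) {
  events <- list()
  for (rep in seq_len(max_events)) {
    one <- topology_step(state, params)
    state <- one$state
    if (is.null(one$event)) break
    events[[length(events) + 1L]] <- one$event
  }
  list(state = state, events = events)
}

# A single topological event: first the smallest sub-threshold cell,
# otherwise a forced retraction of an overstretched cell, otherwise the
# shortest sub-threshold junction.
# Returns list(state, event|NULL).
topology_step <- function(state, params, geom = NULL) {
  if (is.null(geom)) geom <- tissue_geometry(state)
  cool <- attr(state, "repair_cooldown")
  if (is.null(cool)) cool <- numeric(length(state$cells))
  t2c <- find_t2_candidates(state, params, geom)
  t2c <- t2c[cool[t2c] <= state$step]
  for (cell in utils::head(t2c, 3L)) {
    if (length(state$cells[[cell]]) > 3L) {
      # shrink toward a triangle: force a T1 on its shortest eligible edge
      res <- forced_t1(state, cell, params)
      if (!is.null(res)) return(res)
    } else {
      res <- apply_t2(state, cell, params)
      if (res$applied)
        return(list(state = res$state, event = list(
          kind = "T2", step = res$state$step, cells = cell,
          x = res$location[1], y = res$location[2])))
    }
    # repair failed: deeply degenerate cells are collapsed outright,
    # others are retried after a cooldown
    if (geom$area[cell] < 0.5 * params$A_min) {
      res <- apply_t2(state, cell, params, force = TRUE)
      if (res$applied)
        return(list(state = res$state, event = list(
          kind = "T2", step = res$state$step, cells = cell,
          x = res$location[1], y = res$location[2])))
    }
    cool[cell] <- state$step + 15
    attr(state, "repair_cooldown") <- cool
  }
  # cells stretched beyond a third of the box (extreme shear slivers)
  # are retracted through forced intercalations at their ends before
  # their minimum-image geometry can degenerate; a cell that cannot be
  # retracted and keeps stretching is delaminated outright
  over <- utils::head(find_overstretched(state, geom = geom), 3L)
  over <- over[cool[over] <= state$step]
  for (cell in over) {
    res <- forced_t1(state, cell, params)
    if (!is.null(res)) return(res)
    far_gone <- length(overstretched_ids_one(state, geom, cell, 0.38))
    collapsible <- state$class[cell] %in% params$t2_classes ||
      isTRUE(params$hc_t2_allowed)
    if (far_gone && collapsible) {
      res <- apply_t2(state, cell, params, force = TRUE)
      if (res$applied)
        return(list(state = res$state, event = list(
          kind = "T2", step = res$state$step, cells = cell,
          x = res$location[1], y = res$location[2])))
    }
    cool[cell] <- state$step + 15
    attr(state, "repair_cooldown") <- cool
  }
  for (e in find_t1_candidates(state, params, geom)) {
    res <- apply_t1(state, e, params)
    if (res$applied)
      return(list(state = res$state, event = list(
        kind = "T1", step = res$state$step, cells = res$cells,
        x = res$location[1], y = res$location[2])))
  }
  list(state = state, event = NULL)
}

find_overstretched <- function(state, frac = 0.3, geom = NULL) {
  if (is.null(geom)) geom <- tissue_geometry(state)
  overstretched_ids(state, geom, frac)
}

overstretched_ids_one <- function(state, geom, cell, frac) {
  sl <- tissue_slots(state)
  ci <- match(cell, sl$alive_ids)
  rng <- sl$starts[ci]:sl$ends[ci]
  if (cell_oversized(state, geom, rng, frac)) cell else integer(0)
}

# Cells whose unwrapped bounding box exceeds frac * domain on either
# axis, most-stretched first. A cheap perimeter screen avoids per-cell
# work in the common case where no cell is anywhere near the bound.
overstretched_ids <- function(state, geom, frac) {
  if (is.null(state$domain)) return(integer(0))
  bound <- frac * min(state$domain[[1]], state$domain[[2]])
  suspects <- which(state$alive & !is.na(geom$perim) &
                      geom$perim > 2 * bound)
  if (!length(suspects)) return(integer(0))
  sl <- tissue_slots(state)
  ext <- vapply(suspects, function(cell) {
    ci <- match(cell, sl$alive_ids)
    rng <- sl$starts[ci]:sl$ends[ci]
    max(diff(range(geom$ux[rng])) / state$domain[[1]],
        diff(range(geom$uy[rng])) / state$domain[[2]])
  }, numeric(1))
  hit <- ext > frac
  suspects[hit][order(ext[hit], decreasing = TRUE)]
}

# Force a T1 on the shortest eligible edge of a cell (used to shrink
# sub-threshold cells toward triangles and to retract shear slivers).
forced_t1 <- function(state, cell, params, max_tries = 3L) {
  ed <- tissue_edges(state)
  own <- which(ed[, "c1"] == cell | ed[, "c2"] == cell)
  own <- own[!pillar_edge(state)[own]]
  own <- utils::head(own[order(edge_lengths(state)[own])], max_tries)
  for (e in own) {
    res <- apply_t1(state, e, params)
    if (res$applied)
      return(list(state = res$state, event = list(
        kind = "T1", step = res$state$step, cells = res$cells,
        x = res$location[1], y = res$location[2])))
  }
  NULL
}
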