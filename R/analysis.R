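#' Bond-orientational hexagonal order parameter
#'
#' `psi6 = |(1/N) sum_k exp(6 i theta_k)|` over the angles between each
#' neighbor displacement and the x-axis. Equals 1 when the neighbors form
#' a regular hexagon (any rotation) and is close to 0 for uncorrelated
#' points.
#'
#' @param center length-2 numeric, the reference point.
#' @param neighbors n x 2 matrix of neighbor positions.
#' @return a number in `[0, 1]`.
#' @export
psi6 <- function(center, neighbors) {
  neighbors <- rbind(neighbors)
  dx <- neighbors[, 1] - center[1]
  dy <- neighbors[, 2] - center[2]
  if (any(dx == 0 & dy == 0))
    abort_cfg("neighbor coincides with the center point")
  th <- atan2(dy, dx)
  Mod(mean(exp(6i * th)))
}

# Exact Voronoi-facet adjacency of a planar point set.
# Two points are neighbors iff their Voronoi regions share a facet of
# positive length (zero-length corner contacts, as between diagonal cells
# of an exact square grid, do not count). Points on the convex hull have
# unbounded regions and are flagged as boundary.
# Returns list(pairs = 2-col matrix of indices, boundary = logical).
voronoi_adjacency <- function(xy, tol = 1e-9) {
  xy <- unname(as.matrix(xy))
  n <- nrow(xy)
  if (n < 3) abort_cfg("need at least 3 points")
  if (qr(sweep(xy, 2, colMeans(xy)))$rank < 2)
    abort_cfg("degenerate (collinear) point set")
  scale <- stats::median(stats::dist(xy[seq_len(min(n, 60)), ]))
  pairs <- utils::combn(n, 2)
  keep <- logical(ncol(pairs))
  for (pi in seq_len(ncol(pairs))) {
    i <- pairs[1, pi]; j <- pairs[2, pi]
    m <- (xy[i, ] + xy[j, ]) / 2
    d <- xy[j, ] - xy[i, ]
    nh <- c(-d[2], d[1]) / sqrt(sum(d * d))
    others <- setdiff(seq_len(n), c(i, j))
    po <- xy[others, , drop = FALSE]
    a <- 2 * (po[, 1] - xy[i, 1]) * nh[1] + 2 * (po[, 2] - xy[i, 2]) * nh[2]
    b <- (po[, 1] - m[1])^2 + (po[, 2] - m[2])^2 -
      sum((m - xy[i, ])^2)
    lo <- suppressWarnings(max(-Inf, (b / a)[a < 0]))
    hi <- suppressWarnings(min(Inf, (b / a)[a > 0]))
    feasible <- all(b[a == 0] >= -tol * scale^2)
    keep[pi] <- feasible && (hi - lo > tol * scale)
  }
  boundary <- rep(FALSE, n)
  boundary[unique(grDevices::chull(xy))] <- TRUE
  list(pairs = t(pairs[, keep, drop = FALSE]), boundary = boundary)
}

#' Hair-cell neighbor graph from centroids
#'
#' Neighbors are cells sharing a junction (a positive-length facet) in
#' the Voronoi tessellation of the hair-cell centroids. For patterns that
#' wrap around a periodic x-axis, pass `tile_x` so the set is tiled with
#' `+/- tile_x` images before tessellating; adjacency and boundary flags
#' are reported for the central copy.
#'
#' @param pts a centroid tibble with at least columns `id`, `class`, `x`,
#'   `y`; only rows with `class == "HC"` are used.
#' @param tile_x optional period of the x-axis.
#' @return list with `ids` (HC ids), `adjacency` (named list: for each HC
#'   id the vector of neighboring HC ids) and `boundary` (named logical:
#'   unbounded Voronoi region).
#' @export
hc_neighbor_graph <- function(pts, tile_x = NULL) {
  hc <- pts[pts$class == "HC", , drop = FALSE]
  n <- nrow(hc)
  if (n < 3) abort_cfg("need at least 3 hair cells")
  xy <- cbind(hc$x, hc$y)
  idx <- seq_len(n)
  if (!is.null(tile_x)) {
    xy <- rbind(xy, cbind(hc$x - tile_x, hc$y), cbind(hc$x + tile_x, hc$y))
    idx <- rep(idx, 3)
  }
  va <- voronoi_adjacency(xy)
  pr <- va$pairs
  # keep pairs with at least one endpoint in the central copy
  central <- pr[, 1] <= n | pr[, 2] <= n
  pr <- pr[central, , drop = FALSE]
  adj <- lapply(seq_len(n), function(i) {
    hits <- c(idx[pr[pr[, 1] <= n & pr[, 1] == i, 2]],
              idx[pr[pr[, 2] <= n & pr[, 2] == i, 1]])
    hits <- setdiff(hits, i)  # a cell may abut its own periodic image
    sort(unique(hc$id[hits]))
  })
  names(adj) <- as.character(hc$id)
  boundary <- va$boundary[seq_len(n)]
  names(boundary) <- as.character(hc$id)
  list(ids = hc$id, adjacency = adj, boundary = boundary)
}

# Direct least-squares ellipse fit (Fitzgibbon); returns the major/minor
# axis ratio and the major-axis angle, or NULL when the fit degenerates.
fit_ellipse_ratio <- function(xy) {
  xy <- unname(as.matrix(xy))
  if (nrow(xy) < 5) return(NULL)
  ctr <- colMeans(xy)
  x <- xy[, 1] - ctr[1]; y <- xy[, 2] - ctr[2]
  sc <- max(stats::sd(x), stats::sd(y), 1e-12)
  x <- x / sc; y <- y / sc
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T1)) return(NULL)
  M <- S1 + S2 %*% T1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) -
    Re(ev$vectors[2, ])^2
  ok <- which(cond > 0)
  if (!length(ok)) return(NULL)
  a1 <- Re(ev$vectors[, ok[1]])
  A <- a1[1]; B <- a1[2]; C <- a1[3]
  # axis ratio from the quadratic-form eigenvalues
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  lam <- eigen(Q, symmetric = TRUE)
  if (any(lam$values <= 0) && any(lam$values >= 0) &&
      prod(lam$values) <= 0) return(NULL)
  ratio <- sqrt(max(abs(lam$values)) / min(abs(lam$values)))
  minor_vec <- lam$vectors[, which.max(abs(lam$values))]
  major_vec <- lam$vectors[, which.min(abs(lam$values))]
  list(ratio = ratio, angle = atan2(major_vec[2], major_vec[1]))
}

#' Stretch-corrected hexagonal order of hair cells
#'
#' For each analyzed middle-row (OHC2) hair cell: the main axis is a
#' total-least-squares line through the cell and its OHC2 Voronoi
#' neighbors; an ellipse is fitted to the neighboring hair-cell
#' centroids and its major/minor ratio `r_e_fit` acquired; the neighbor
#' positions are squeezed by `r_e_fit` along the main axis; `psi6` of the
#' rescaled positions is returned. Falls back to a second-moment ratio
#' when fewer than 5 neighbors determine the ellipse. Cells with fewer
#' than 3 neighbors, or with unbounded Voronoi regions, are excluded.
#'
#' @param pts a centroid tibble (`id`, `class`, `x`, `y`, optionally
#'   `row`); rows are classified on the fly when absent.
#' @param cells ids of the cells to analyze (default: every interior
#'   OHC2 hair cell).
#' @param tile_x optional x-period (see [hc_neighbor_graph()]).
#' @return a tibble: `id`, `psi6_star`, `psi6_raw`, `r_e_fit`,
#'   `axis_angle`, `n_neighbors`.
#' @export
psi6_star <- function(pts, cells = NULL, tile_x = NULL) {
  if (!"row" %in% names(pts)) pts <- classify_rows(pts)$pts
  gr <- hc_neighbor_graph(pts, tile_x = tile_x)
  hc <- pts[pts$class == "HC", ]
  if (is.null(cells))
    cells <- hc$id[hc$row == "OHC2" & !gr$boundary[as.character(hc$id)]]
  rows <- lapply(cells, function(cid) {
    nb <- gr$adjacency[[as.character(cid)]]
    if (length(nb) < 3) return(NULL)
    ctr <- c(hc$x[hc$id == cid], hc$y[hc$id == cid])
    nxy <- cbind(hc$x[match(nb, hc$id)], hc$y[match(nb, hc$id)])
    if (!is.null(tile_x))  # bring neighbors into the center's image
      nxy[, 1] <- ctr[1] + min_image(nxy[, 1] - ctr[1], tile_x)
    # main axis: TLS line through the cell and its OHC2 neighbors
    o2 <- nb[hc$row[match(nb, hc$id)] == "OHC2"]
    axis_pts <- rbind(ctr, nxy[match(o2, nb), , drop = FALSE])
    u <- if (nrow(axis_pts) >= 2) {
      e <- eigen(stats::cov(axis_pts), symmetric = TRUE)
      e$vectors[, 1]
    } else c(1, 0)
    fit <- fit_ellipse_ratio(nxy)
    r <- if (!is.null(fit)) fit$ratio else {
      rel <- sweep(nxy, 2, ctr)
      along <- rel %*% u
      perp <- rel %*% c(-u[2], u[1])
      max(1, sqrt(mean(along^2) / max(mean(perp^2), 1e-12)))
    }
    r <- max(r, 1)
    rel <- sweep(nxy, 2, ctr)
    along <- drop(rel %*% u) / r
    perp <- drop(rel %*% c(-u[2], u[1]))
    squeezed <- cbind(along * u[1] - perp * u[2],
                      along * u[2] + perp * u[1])
    tibble::tibble(id = cid,
                   psi6_star = psi6(c(0, 0), squeezed),
                   psi6_raw = psi6(c(0, 0), rel),
                   r_e_fit = r,
                   axis_angle = atan2(u[2], u[1]),
                   n_neighbors = length(nb))
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out))
    out <- tibble::tibble(id = integer(), psi6_star = numeric(),
                          psi6_raw = numeric(), r_e_fit = numeric(),
                          axis_angle = numeric(), n_neighbors = integer())
  out
}

#' Classify hair cells into OHC rows
#'
#' With a mesh: hair cells sharing a junction with the pillar row are
#' OHC1, those touching the top border (or unlabeled lateral outside
#' cells) are OHC3, the rest OHC2. With a bare centroid table the rows
#' come from 1D gap clustering of the hair-cell y-coordinates (gaps wider
#' than half the median hair-cell spacing split bands): the band nearest
#' the pillar side is OHC1, the farthest OHC3, intermediate bands OHC2.
#'
#' @param x a `corti_tissue` or a centroid tibble.
#' @param gap_factor gap threshold in units of the median HC spacing.
#' @return list with `pts` (centroid tibble gaining a `row` column for
#'   hair cells) and `n_rows` (number of y-bands found).
#' @export
classify_rows <- function(x, gap_factor = 0.5) {
  if (inherits(x, "corti_tissue")) {
    pts <- as_centroid_tibble(x)
    is_hc <- pts$class == "HC"
    t_pillar <- touches_class(x, c("pillar", "IHC"))[pts$id]
    t_top <- touches_class(x, c("top_boundary", "outside"))[pts$id]
    row <- rep(NA_character_, nrow(pts))
    row[is_hc] <- "OHC2"
    row[is_hc & t_top] <- "OHC3"
    row[is_hc & t_pillar] <- "OHC1"
    pts$row <- row
    yrel <- min_image(pts$y - x$y0, x$domain[[2]])
    spacing <- median_nn_spacing(cbind(pts$x[is_hc], yrel[is_hc]))
    n_rows <- count_bands(yrel[is_hc], gap_factor, spacing)
    return(list(pts = pts, n_rows = n_rows))
  }
  pts <- x
  is_hc <- pts$class == "HC"
  ys <- pts$y[is_hc]
  spacing <- median_nn_spacing(cbind(pts$x[is_hc], ys))
  n_rows <- count_bands(ys, gap_factor, spacing)
  band <- band_index(ys, gap_factor, spacing)
  row <- rep(NA_character_, nrow(pts))
  lab <- rep("OHC2", n_rows)
  lab[1] <- "OHC1"
  if (n_rows > 1) lab[n_rows] <- "OHC3"
  row[is_hc] <- lab[band]
  pts$row <- row
  list(pts = pts, n_rows = n_rows)
}

band_index <- function(ys, gap_factor = 0.5, spacing = NULL) {
  if (!length(ys)) return(integer(0))
  if (is.null(spacing)) spacing <- median_nn_spacing(ys)
  o <- order(ys)
  gaps <- diff(ys[o])
  band_sorted <- cumsum(c(1, as.integer(gaps > gap_factor * spacing)))
  band <- integer(length(ys))
  band[o] <- band_sorted
  band
}

count_bands <- function(ys, gap_factor = 0.5, spacing = NULL) {
  if (!length(ys)) return(0L)
  max(band_index(ys, gap_factor, spacing))
}

# Median nearest-neighbor spacing of a 1D or 2D point set.
median_nn_spacing <- function(p) {
  p <- cbind(p)
  if (nrow(p) < 2) return(1)
  d <- as.matrix(stats::dist(p))
  diag(d) <- Inf
  stats::median(apply(d, 1, min))
}

# Hair cells eligible for statistics: alive HCs not touching the pillar
# cells or the top border (or unlabeled outside cells).
analysis_hcs <- function(state) {
  excl <- touches_class(state, c("pillar", "IHC", "top_boundary", "outside"))
  which(state$alive & state$class == "HC" & !excl)
}

#' Supporting-cell neighbor counts of hair cells
#'
#' Counts, for each hair cell, the junction-sharing neighbors of each
#' class in the mesh, with the exclusion flags used by the aggregate
#' statistics (touching the pillar row or the top border).
#'
#' @param state a `corti_tissue`.
#' @return a tibble: `id`, `row`, `n_sc`, `n_hc`, `n_neighbors`,
#'   `excluded`.
#' @export
sc_neighbor_count <- function(state) {
  hc <- which(state$alive & state$class == "HC")
  ad <- cell_adjacency(state)
  both <- rbind(ad, ad[, 2:1])
  nb_class <- state$class[both[, 2]]
  n_sc <- rowsum_full(as.numeric(nb_class == "SC"), both[, 1],
                      length(state$cells))
  n_all <- rowsum_full(rep(1, nrow(both)), both[, 1], length(state$cells))
  n_hc <- rowsum_full(as.numeric(nb_class == "HC"), both[, 1],
                      length(state$cells))
  cr <- classify_rows(state)
  rowlab <- cr$pts$row[match(hc, cr$pts$id)]
  excl <- !(hc %in% analysis_hcs(state))
  tibble::tibble(id = hc, row = rowlab, n_sc = n_sc[hc], n_hc = n_hc[hc],
                 n_neighbors = n_all[hc], excluded = excl)
}

#' Mean HC/SC area ratio
#'
#' The area of each analyzed hair cell is divided by the area of each of
#' its adjacent supporting cells (multiple values per hair cell); the
#' mean of all such pair ratios is returned. Hair cells touching the
#' pillar row or the top border are excluded.
#'
#' @param state a `corti_tissue`.
#' @param pairs if `TRUE`, return the per-pair tibble instead of the mean.
#' @return a number, or a tibble (`hc`, `sc`, `ratio`) when
#'   `pairs = TRUE`.
#' @export
area_ratio <- function(state, pairs = FALSE) {
  hc <- analysis_hcs(state)
  if (!length(hc)) return(if (pairs) tibble::tibble() else NA_real_)
  g <- tissue_geometry(state)
  ad <- cell_adjacency(state)
  both <- rbind(ad, ad[, 2:1])
  sel <- both[, 1] %in% hc & state$class[both[, 2]] == "SC"
  tb <- tibble::tibble(hc = both[sel, 1], sc = both[sel, 2],
                       ratio = g$area[both[sel, 1]] / g$area[both[sel, 2]])
  if (pairs) tb else mean(tb$ratio)
}

#' Straighten a curved row of hair cells
#'
#' Iteratively aligns a curved (e.g. spiral-shaped) pattern with the
#' x-axis: walking along the ordered middle-row backbone from base to
#' apex, the local tilt is estimated from the mean position of the
#' apex-ward Voronoi neighbors of the current origin cell, and all
#' apex-ward hair cells are rotated about the origin by the negative of
#' that angle. Every update is a rigid rotation of a subset, so pairwise
#' distances within the rotated subset are preserved.
#'
#' @param pts centroid tibble (hair cells are straightened; other rows
#'   pass through unchanged).
#' @param backbone ids of the middle-row cells ordered base to apex;
#'   default: OHC2 cells ordered by x.
#' @return the centroid tibble with hair-cell positions straightened.
#' @export
straighten_centroids <- function(pts, backbone = NULL) {
  if (!"row" %in% names(pts)) pts <- classify_rows(pts)$pts
  hc_sel <- which(pts$class == "HC")
  if (is.null(backbone)) {
    o2 <- hc_sel[pts$row[hc_sel] == "OHC2"]
    backbone <- pts$id[o2[order(pts$x[o2])]]
  }
  # base-to-apex position of every hair cell: its own backbone rank, or
  # the rank of the nearest backbone cell
  gr <- tryCatch(hc_neighbor_graph(pts), error = function(e) NULL)
  x <- pts$x; y <- pts$y
  bidx <- match(backbone, pts$id)
  rank_of <- function() {
    vapply(hc_sel, function(i) {
      d2 <- (x[bidx] - x[i])^2 + (y[bidx] - y[i])^2
      which.min(d2)
    }, integer(1))
  }
  for (k in seq_along(backbone)) {
    bi <- bidx[k]
    ox <- x[bi]; oy <- y[bi]
    rk <- rank_of()
    apexward <- hc_sel[rk > k]
    nb <- if (!is.null(gr)) gr$adjacency[[as.character(backbone[k])]]
          else pts$id[c(bidx[k - 1][k > 1], bidx[k + 1][k < length(backbone)])]
    nbi <- match(nb, pts$id)
    apexward_nb <- intersect(nbi, apexward)
    if (!length(apexward_nb)) next
    mx <- mean(x[apexward_nb]) - ox
    my <- mean(y[apexward_nb]) - oy
    th <- atan2(my, mx)
    dx <- x[apexward] - ox; dy <- y[apexward] - oy
    x[apexward] <- ox + cos(-th) * dx - sin(-th) * dy
    y[apexward] <- oy + sin(-th) * dx + cos(-th) * dy
  }
  pts$x <- x; pts$y <- y
  pts
}

#' Structure factor of a point pattern
#'
#' `S(q) = (1/N) sum_jk exp(-i q . (r_j - r_k))`, evaluated as
#' `|sum_j exp(-i q . r_j)|^2 / N` on a square grid of wave vectors.
#' `S(0) = N` exactly; Bragg peaks at reciprocal-lattice vectors indicate
#' crystalline order.
#'
#' @param pts centroid tibble (all rows used; filter beforehand for
#'   HC-only spectra) or an n x 2 matrix.
#' @param q_max grid half-width; default four times the first
#'   reciprocal-lattice magnitude `2 pi / a` with `a` the median
#'   nearest-neighbor spacing.
#' @param n_q grid points per axis (odd values include q = 0).
#' @return a tibble: `qx`, `qy`, `S`.
#' @export
structure_factor <- function(pts, q_max = NULL, n_q = 65) {
  xy <- if (is.matrix(pts)) pts else cbind(pts$x, pts$y)
  n <- nrow(xy)
  if (is.null(q_max)) q_max <- 4 * 2 * pi / median_nn_spacing(xy)
  qs <- seq(-q_max, q_max, length.out = n_q)
  grid <- expand.grid(qx = qs, qy = qs)
  phase <- exp(-1i * (outer(grid$qx, xy[, 1]) + outer(grid$qy, xy[, 2])))
  S <- Mod(rowSums(phase))^2 / n
  tibble::tibble(qx = grid$qx, qy = grid$qy, S = S)
}

#' Event rate per cell per unit time
#'
#' Number of events of the given kind divided by the OHC-region cell
#' count and the duration, mirroring how intercalation rates are
#' extracted from the movies.
#'
#' @param trajectory a `corti_trajectory`, or an event tibble.
#' @param kind `"T1"`, `"T2"` or `"differentiation"`.
#' @param n_cells region cell count; defaults to the number of hair and
#'   supporting cells in the trajectory's final state.
#' @param duration time span; defaults to the trajectory's step span.
#' @return events per cell per step.
#' @export
count_events <- function(trajectory, kind = "T1", n_cells = NULL,
                         duration = NULL) {
  ev <- if (inherits(trajectory, "corti_trajectory")) trajectory$events
        else trajectory
  if (is.null(n_cells)) {
    st <- trajectory$final
    n_cells <- sum(st$alive & st$class %in% c("HC", "SC"))
  }
  if (is.null(duration))
    duration <- trajectory$final$step - trajectory$snapshots[[1]]$step
  if (n_cells <= 0 || duration <= 0) abort_cfg("empty region or duration")
  sum(ev$kind == kind) / (n_cells * duration)
}

#' Displacement profiles in the pillar-row frame
#'
#' Per-snapshot centroid displacement of each cell from its initial
#' position, with the mean displacement of the pillar row subtracted
#' (the pillar row is the static reference frame). Group means and SEM
#' are reported for hair and supporting cells split by their initial
#' position in the medial or lateral half of the OHC region.
#'
#' @param trajectory a `corti_trajectory`.
#' @return a tibble: `step`, `class`, `half`, `mean_dx`, `mean_dy`,
#'   `sem_dx`, `sem_dy`, `n`.
#' @export
displacement_profiles <- function(trajectory) {
  snaps <- trajectory$snapshots
  s0 <- snaps[[1]]
  g0 <- tissue_geometry(s0)
  final <- trajectory$final
  ids <- which(s0$alive & final$alive[seq_along(s0$alive)] &
                 final$class %in% c("HC", "SC"))
  y0rel <- min_image(g0$centroid[ids, 2] - s0$y0, s0$domain[[2]])
  half <- ifelse(y0rel <= stats::median(y0rel), "medial", "lateral")
  cls <- final$class[ids]
  pillar <- which(s0$alive & s0$class == "pillar")
  rows <- lapply(snaps, function(s) {
    g <- tissue_geometry(s)
    dx <- min_image(g$centroid[, 1] - g0$centroid[, 1], s0$domain[[1]])
    dy <- min_image(g$centroid[, 2] - g0$centroid[, 2], s0$domain[[2]])
    dx_ref <- mean(dx[pillar]); dy_ref <- mean(dy[pillar])
    tibble::tibble(step = s$step, class = cls, half = half,
                   dx = dx[ids] - dx_ref, dy = dy[ids] - dy_ref)
  })
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$step, .data$class, .data$half) |>
    dplyr::summarise(
      mean_dx = mean(.data$dx), mean_dy = mean(.data$dy),
      sem_dx = stats::sd(.data$dx) / sqrt(dplyr::n()),
      sem_dy = stats::sd(.data$dy) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop")
}

#' Order parameters of one state
#'
#' One-row summary used as the per-snapshot metric record: hair-cell
#' count, mean SC-neighbor count and mean stretch-corrected hexagonal
#' order over the analyzed hair cells, HC/SC area ratio, and the number
#' of hair-cell rows.
#'
#' @param state a `corti_tissue`.
#' @return a one-row tibble.
#' @export
tissue_metrics <- function(state) {
  hc <- which(state$alive & state$class == "HC")
  nc <- sc_neighbor_count(state)
  ok <- !nc$excluded
  mean_sc <- if (any(ok)) mean(nc$n_sc[ok]) else NA_real_
  cr <- classify_rows(state)
  psi <- tryCatch({
    ids <- nc$id[!nc$excluded & nc$row == "OHC2"]
    if (length(ids) >= 1) {
      ps <- psi6_star(cr$pts, cells = ids, tile_x = state$domain[[1]])
      if (nrow(ps)) mean(ps$psi6_star) else NA_real_
    } else NA_real_
  }, error = function(e) NA_real_)
  tibble::tibble(step = state$step, n_cells = sum(state$alive),
                 n_hc = length(hc), mean_sc_neighbors = mean_sc,
                 mean_psi6_star = psi, area_ratio = area_ratio(state),
                 hc_rows = cr$n_rows)
}
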