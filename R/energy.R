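#' Total mechanical energy of the tissue
#'
#' Sums, over all alive cells, the four energy terms of the model: quadratic
#' area elasticity `1/2 alpha (A - A0)^2`, junctional line tension
#' `sum gamma l` (each physical junction is counted once per owning cell,
#' i.e. twice in total, following the per-cell sum convention), quadratic
#' perimeter contractility `1/2 Gamma L^2`, and the steric hair-cell
#' repulsion `sum sigma (D/R)^kappa` over ordered HC pairs.
#'
#' @param state a `corti_tissue`.
#' @param params a `corti_params`.
#' @param terms if `TRUE`, return the named per-term breakdown instead of
#'   the total.
#' @return a number (energy units), or a named vector when `terms = TRUE`.
#' @export
total_energy <- function(state, params, terms = FALSE) {
  g <- tissue_geometry(state)
  sl <- tissue_slots(state)
  cl <- state$class
  alive <- which(state$alive)

  A0 <- params$A0[cl[alive]] * state$A0_scale[alive]
  e_area <- sum(0.5 * params$alpha[cl[alive]] * (g$area[alive] - A0)^2)

  gmat <- gamma_matrix(params)
  gam_slot <- gmat[cbind(cl[sl$cell], cl[sl$other_cell])] *
    state$edge_gamma_scale[sl$eid]
  e_tension <- sum(gam_slot * g$len)

  e_perim <- sum(0.5 * params$Gamma[cl[alive]] * state$Gamma_scale[alive] *
                   g$perim[alive]^2)

  e_rep <- repulsion_energy(state, params, geom = g)

  out <- c(area = e_area, tension = e_tension, perimeter = e_perim,
           repulsion = e_rep)
  if (terms) out else sum(out)
}

#' Steric repulsion energy between hair cells
#'
#' `sum sigma (D/R_nm)^kappa` over ordered pairs of distinct hair cells
#' (each unordered pair therefore contributes twice). Distances between
#' centroids use the minimum-image convention on periodic axes when
#' `params$repulsion_min_image` is `TRUE`.
#'
#' @inheritParams total_energy
#' @param geom internal: precomputed `tissue_geometry(state)`.
#' @return a number.
#' @export
repulsion_energy <- function(state, params, geom = NULL) {
  if (params$sigma == 0) return(0)
  hc <- which(state$alive & state$class == "HC")
  if (length(hc) < 2) return(0)
  if (is.null(geom)) geom <- tissue_geometry(state)
  ctr <- geom$centroid[hc, , drop = FALSE]
  d <- hc_pair_disp(ctr, state, params)
  R2 <- d$dx^2 + d$dy^2
  if (any(R2 == 0)) abort_topology("coincident hair-cell centroids")
  2 * params$sigma * sum((params$D^2 / R2)^(params$kappa / 2))
}

# Unordered HC pair displacements (i < j), optionally minimum-image.
hc_pair_disp <- function(ctr, state, params) {
  n <- nrow(ctr)
  i <- rep.int(seq_len(n - 1), (n - 1):1)
  j <- sequence((n - 1):1, from = 2:n)
  dx <- ctr[j, 1] - ctr[i, 1]
  dy <- ctr[j, 2] - ctr[i, 2]
  if (params$repulsion_min_image && !is.null(state$domain)) {
    dx <- min_image(dx, state$domain[[1]])
    dy <- min_image(dy, state$domain[[2]])
  }
  list(i = i, j = j, dx = dx, dy = dy)
}

#' External shear and compression forces
#'
#' For every vertex of every hair cell, adds the global shear force
#' `eta * y_cm` along +x and the compression force
#' `zeta * y_cm * grad_i(y_cm)` (with the vertex-mean centroid,
#' `grad_i(y_cm) = y_hat / k`). `y_cm` is measured from the
#' pillar-row/OHC interface `state$y0`. Non-hair cells contribute nothing;
#' a vertex shared with a hair cell receives that cell's contribution.
#'
#' @inheritParams repulsion_energy
#' @return an n_vertices x 2 force matrix.
#' @export
external_force <- function(state, params, geom = NULL) {
  nv <- nrow(state$pos)
  F <- matrix(0, nv, 2)
  if (params$eta == 0 && params$zeta == 0) return(F)
  if (is.null(geom)) geom <- tissue_geometry(state)
  sl <- tissue_slots(state)
  is_hc_slot <- state$class[sl$cell] == "HC"
  if (!any(is_hc_slot)) return(F)
  ycm <- geom$centroid[, 2] - state$y0
  if (!is.null(state$domain)) ycm <- min_image(ycm, state$domain[[2]])
  yc <- ycm[sl$cell[is_hc_slot]]
  kc <- geom$k[sl$cell[is_hc_slot]]
  vtx <- sl$v[is_hc_slot]
  F[, 1] <- F[, 1] + rowsum_full(params$eta * yc, vtx, nv)
  F[, 2] <- F[, 2] + rowsum_full(params$zeta * yc / kc, vtx, nv)
  F
}

#' Analytic force field -grad E
#'
#' The negative gradient of [total_energy()] with respect to the flattened
#' vertex position vector, computed analytically (shoelace derivative for
#' the area term, unit-vector sums for tension and perimeter, centroid
#' chain rule for the repulsion). Verified against central finite
#' differences in the test suite.
#'
#' @inheritParams repulsion_energy
#' @return an n_vertices x 2 matrix holding `-grad E`.
#' @export
energy_gradient <- function(state, params, geom = NULL) {
  if (is.null(geom)) geom <- tissue_geometry(state)
  sl <- tissue_slots(state)
  cl <- state$class
  nv <- nrow(state$pos)

  dx <- geom$dx; dy <- geom$dy; len <- geom$len
  inv_len <- ifelse(len > 0, 1 / len, 0)   # zero-length edge: no direction
  ux_hat <- dx * inv_len; uy_hat <- dy * inv_len
  dxp <- dx[sl$prv_idx]; dyp <- dy[sl$prv_idx]
  uxp <- ux_hat[sl$prv_idx]; uyp <- uy_hat[sl$prv_idx]

  # area term: dE/dv_i = alpha (A - A0) * (0.5*(dy_i + dy_{i-1}),
  #                                        -0.5*(dx_i + dx_{i-1}))
  A0 <- params$A0[cl] * state$A0_scale
  ca <- params$alpha[cl] * (geom$area - A0)   # per cell (NA for dead)
  ca_slot <- ca[sl$cell]
  gx <- ca_slot * 0.5 * (dy + dyp)
  gy <- ca_slot * (-0.5) * (dx + dxp)

  # perimeter term: dE/dv_i = Gamma L (u_hat_{i-1} - u_hat_i)
  cp <- params$Gamma[cl] * state$Gamma_scale * geom$perim
  cp_slot <- cp[sl$cell]
  gx <- gx + cp_slot * (uxp - ux_hat)
  gy <- gy + cp_slot * (uyp - uy_hat)

  # tension: each directed slot (v -> nxt) with tension t pulls both ends
  gmat <- gamma_matrix(params)
  t_slot <- gmat[cbind(cl[sl$cell], cl[sl$other_cell])] *
    state$edge_gamma_scale[sl$eid]
  tp <- t_slot[sl$prv_idx]
  gx <- gx + tp * uxp - t_slot * ux_hat
  gy <- gy + tp * uyp - t_slot * uy_hat

  G <- matrix(0, nv, 2)
  G[, 1] <- rowsum_full(gx, sl$v, nv)
  G[, 2] <- rowsum_full(gy, sl$v, nv)

  # repulsion: per unordered pair, dE = 2 sigma (D/R)^kappa
  if (params$sigma > 0) {
    hc <- which(state$alive & cl == "HC")
    if (length(hc) >= 2) {
      ctr <- geom$centroid[hc, , drop = FALSE]
      d <- hc_pair_disp(ctr, state, params)
      R2 <- d$dx^2 + d$dy^2
      if (any(R2 == 0)) abort_topology("coincident hair-cell centroids")
      w <- 2 * params$sigma * params$kappa *
        (params$D^2 / R2)^(params$kappa / 2) / R2
      fmax <- params$repulsion_fmax %||% Inf
      if (is.finite(fmax)) w <- pmin(w, fmax / sqrt(R2))
      # +dE/dcentroid: pair energy falls with R, so dE/dc_i = +w * r_ij
      fx <- w * d$dx; fy <- w * d$dy
      nh <- length(hc)
      Fcx <- rowsum_full(c(fx, -fx), c(d$i, d$j), nh)
      Fcy <- rowsum_full(c(fy, -fy), c(d$i, d$j), nh)
      # distribute -dE/dcentroid to the cell's vertices (vertex-mean)
      cell_fx <- numeric(length(state$cells)); cell_fy <- cell_fx
      cell_fx[hc] <- Fcx / geom$k[hc]
      cell_fy[hc] <- Fcy / geom$k[hc]
      is_hc_slot <- cl[sl$cell] == "HC"
      G[, 1] <- G[, 1] + rowsum_full(cell_fx[sl$cell[is_hc_slot]],
                                     sl$v[is_hc_slot], nv)
      G[, 2] <- G[, 2] + rowsum_full(cell_fy[sl$cell[is_hc_slot]],
                                     sl$v[is_hc_slot], nv)
    }
  }
  -G  # G accumulates +dE/dv; the force field is -grad E
}

#' Uniform vertex noise force
#'
#' i.i.d. per-component draws, uniform on `[-f_noise, f_noise]`. The
#' simulation loop resamples this field every `k_noise` steps and holds it
#' constant in between.
#'
#' @inheritParams repulsion_energy
#' @return an n_vertices x 2 matrix.
#' @export
noise_force <- function(state, params) {
  nv <- nrow(state$pos)
  if (params$f_noise == 0) return(matrix(0, nv, 2))
  matrix(stats::runif(2 * nv, -params$f_noise, params$f_noise), nv, 2)
}

#' One gradient-descent update of the vertex positions
#'
#' Displaces all vertices simultaneously by
#' `epsilon * (-grad E + F_ext + F_noise)` and wraps them into the
#' periodic domain. If the update inverts any cell, the displacement is
#' retried with a halved step up to `max_halvings` times before erroring.
#' Topology is untouched; transitions are handled separately.
#'
#' @inheritParams repulsion_energy
#' @param noise optional precomputed noise field (held between refreshes).
#' @param max_halvings retry budget when a cell inverts.
#' @param on_fail after the retry budget: `"error"` (default), or
#'   `"freeze"` to reject the displacement and keep positions unchanged
#'   for this step (used by the protocol loop, where a topological event
#'   normally resolves the infeasibility within a few steps).
#' @return the updated `corti_tissue`.
#' @export
step_tissue <- function(state, params, noise = NULL, max_halvings = 8L,
                        on_fail = c("error", "freeze")) {
  on_fail <- match.arg(on_fail)
  sl <- tissue_slots(state)
  dom <- if (is.null(state$domain)) numeric(0) else as.numeric(state$domain)
  cl <- state$class
  gmat <- gamma_matrix(params)
  t_slot <- gmat[cbind(cl[sl$cell], cl[sl$other_cell])] *
    state$edge_gamma_scale[sl$eid]
  n_cells <- length(state$cells)
  alpha_eff <- unname(params$alpha[cl])
  A0_eff <- unname(params$A0[cl]) * state$A0_scale
  Gamma_eff <- unname(params$Gamma[cl]) * state$Gamma_scale
  hc_cells <- which(state$alive & cl == "HC")
  res <- vm_force_cpp(state$pos, sl$v, sl$nxt, sl$prv_idx, sl$cell,
                      sl$starts, sl$k, sl$alive_ids, n_cells, dom,
                      alpha_eff, A0_eff, Gamma_eff, t_slot,
                      hc_cells, params$sigma, params$D, params$kappa,
                      isTRUE(params$repulsion_min_image),
                      params$repulsion_fmax %||% R_PosInf_num(),
                      params$eta, params$zeta, state$y0)
  F <- res$F
  if (!is.null(noise)) F <- F + noise
  pins <- params$pin_classes %||% character(0)
  if (length(pins)) {
    pv <- sl$v[cl[sl$cell] %in% pins]
    if (identical(params$pin_axis %||% "y", "y")) F[pv, 2] <- 0
    else F[pv, ] <- 0
  }
  eps <- params$epsilon
  for (try in 0:max_halvings) {
    newpos <- wrap2(state$pos + eps * F, state$domain)
    a <- vm_areas_cpp(newpos, sl$v, sl$nxt, sl$starts, sl$k,
                      sl$alive_ids, n_cells, dom)
    bad <- which(state$alive & !(is.finite(a) & a > 0))
    if (length(bad)) {
      # cells wrapping around the torus have no well-defined shoelace
      # area; tolerate them (topological events will repair them)
      cand <- state
      cand$pos <- newpos
      g <- tissue_geometry(cand)
      ok <- vapply(bad, function(cell) {
        ci <- match(cell, sl$alive_ids)
        cell_oversized(cand, g, sl$starts[ci]:sl$ends[ci])
      }, logical(1))
      bad <- bad[!ok]
    }
    if (!length(bad)) {
      cand <- state
      cand$pos <- newpos
      cand$step <- state$step + 1L
      return(cand)
    }
    eps <- eps / 2
  }
  if (on_fail == "freeze") {
    state$step <- state$step + 1L
    return(state)
  }
  abort_topology("cell inversion persisted after step halving")
}

# Residual force magnitude (for convergence checks): max over vertices of
# |-grad E + F_ext|.
residual_force <- function(state, params) {
  geom <- tissue_geometry(state)
  F <- energy_gradient(state, params, geom) +
    external_force(state, params, geom)
  used <- unique(tissue_slots(state)$v)
  max(abs(F[used, ]))
}


R_PosInf_num <- function() Inf
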