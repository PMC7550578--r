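#' Mechanical model parameters
#'
#' Builds the full parameter set of the vertex model: per-cell-class area
#' stiffness `alpha`, preferred area `A0` and perimeter contractility
#' `Gamma`; junctional line tensions `gamma` keyed by the unordered pair of
#' incident cell classes; the hair-cell steric repulsion (`sigma`, `D`,
#' `kappa`); external shear `eta` and lateral compression `zeta` acting on
#' hair cells; the gradient-descent step `epsilon` and the vertex noise
#' (`f_noise`, refreshed every `k_noise` steps); and the topological
#' thresholds (`l_min` for intercalations, `A_min` for delaminations, the
#' post-T1 relaxation `lockout`).
#'
#' All quantities are dimensionless; lengths are in units of the initial
#' hexagon side, so the reference cell area is `3*sqrt(3)/2`.
#'
#' Cell classes are `HC`, `SC`, `pillar`, `IHC`, `top_boundary`, `outside`.
#' Junction tensions are looked up as `"A:B"` keys with the two class names
#' sorted alphabetically; `"A:*"` acts as a wildcard for any junction with
#' one `A` side, and explicit pairs take precedence over wildcards, which
#' take precedence over `gamma_default`. The tension of a physical junction
#' enters the energy once per owning cell, i.e. twice in total; defaults
#' are chosen with that convention in mind.
#'
#' @param ... named overrides of any default listed below.
#' @return An object of class `corti_params` (a validated named list).
#' @examples
#' p <- model_params(sigma = 0.1)
#' p$sigma
#' @export
model_params <- function(...) {
  hex_area <- 3 * sqrt(3) / 2
  p <- list(
    # per-class area stiffness: HC apices are less compressible than SC
    alpha = c(HC = 2, SC = 1, pillar = 2, IHC = 2,
              top_boundary = 1, outside = 1),
    # preferred apical areas
    A0 = c(HC = hex_area, SC = hex_area, pillar = hex_area, IHC = hex_area,
           top_boundary = hex_area, outside = hex_area),
    # perimeter contractility: HCs more contractile (rounder)
    Gamma = c(HC = 0.2, SC = 0.04, pillar = 0.06, IHC = 0.1,
              top_boundary = 0.02, outside = 0.02),
    gamma_default = 0.08,
    gamma = c("pillar:*" = 0.5),
    # steric repulsion between HC centroids
    sigma = 0.5, D = 1.9, kappa = 8, repulsion_min_image = TRUE,
    # cap on the repulsive pair force magnitude: the bare power law grows
    # so steeply below D that close encounters (e.g. right after an
    # intercalation) would stall the integrator; the cap softens the core
    # without affecting forces at working distances
    repulsion_fmax = 8,
    # external shear / compression on HCs (zeta < 0 pulls toward pillar row)
    eta = 0.07, zeta = -0.55,
    # integrator
    epsilon = 0.04, f_noise = 0.06, k_noise = 10,
    # topological transitions
    l_min = 0.25, A_min = 0.3, l_new_factor = 1.6, lockout = 20,
    t2_classes = c("SC", "outside"),
    hc_t2_allowed = FALSE,
    t2_extra_cells = integer(0),
    # the pillar row is the static reference frame of the tissue: vertices
    # of these cell classes are held fixed during integration
    pin_classes = "pillar", pin_axis = "y",
    centroid = "vertex_mean"
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      abort_cfg("all parameter overrides must be named")
    bad <- setdiff(names(dots), names(p))
    if (length(bad))
      abort_cfg("unknown parameter(s)", paste(bad, collapse = ", "))
    for (nm in names(dots)) {
      if (nm %in% c("alpha", "A0", "Gamma")) {
        v <- dots[[nm]]
        badc <- setdiff(names(v), names(p[[nm]]))
        if (length(badc))
          abort_cfg("unknown cell class", paste0(nm, ".", badc[1]))
        p[[nm]][names(v)] <- v
      } else if (nm == "gamma") {
        p$gamma[names(dots$gamma)] <- dots$gamma
      } else {
        p[[nm]] <- dots[[nm]]
      }
    }
  }
  validate_params(p)
  structure(p, class = "corti_params")
}

validate_params <- function(p) {
  chk_nonneg <- function(key) {
    if (any(!is.finite(p[[key]])) || any(p[[key]] < 0))
      abort_cfg("must be finite and >= 0", key)
  }
  for (key in c("alpha", "Gamma", "sigma", "D", "epsilon", "f_noise",
                "l_min", "A_min", "lockout", "gamma_default"))
    chk_nonneg(key)
  if (any(p$A0 <= 0)) abort_cfg("preferred areas must be > 0", "A0")
  if (!is.finite(p$kappa) || p$kappa < 2)
    abort_cfg("repulsion exponent must be >= 2", "repulsion.kappa")
  if (p$k_noise < 1) abort_cfg("noise refresh interval must be >= 1", "k_noise")
  if (p$l_new_factor <= 1) abort_cfg("post-T1 length factor must be > 1",
                                     "l_new_factor")
  invisible(p)
}

CELL_CLASSES <- c("HC", "SC", "pillar", "IHC", "top_boundary", "outside")

# Resolve the class-pair tension table into a full symmetric matrix.
gamma_matrix <- function(params) {
  cl <- CELL_CLASSES
  g <- matrix(params$gamma_default, length(cl), length(cl),
              dimnames = list(cl, cl))
  keys <- names(params$gamma)
  # wildcards first, explicit pairs second (precedence)
  for (pass in 1:2) {
    for (k in keys) {
      parts <- strsplit(k, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2)
        abort_cfg("tension keys must look like 'classA:classB'", k)
      wild <- any(parts == "*")
      if ((pass == 1) != wild) next
      if (wild) {
        a <- setdiff(parts, "*")
        if (length(a) != 1 || !a %in% cl) abort_cfg("unknown class in key", k)
        g[a, ] <- params$gamma[[k]]
        g[, a] <- params$gamma[[k]]
      } else {
        if (!all(parts %in% cl)) abort_cfg("unknown class in key", k)
        g[parts[1], parts[2]] <- params$gamma[[k]]
        g[parts[2], parts[1]] <- params$gamma[[k]]
      }
    }
  }
  g
}

#' @export
print.corti_params <- function(x, ...) {
  cat("<corti_params>\n")
  cat("  alpha:", paste0(names(x$alpha), "=", signif(x$alpha, 3),
                         collapse = " "), "\n")
  cat("  Gamma:", paste0(names(x$Gamma), "=", signif(x$Gamma, 3),
                         collapse = " "), "\n")
  cat("  gamma_default:", x$gamma_default,
      " overrides:", paste0(names(x$gamma), "=", signif(x$gamma, 3),
                            collapse = " "), "\n")
  cat("  repulsion: sigma=", x$sigma, " D=", x$D, " kappa=", x$kappa, "\n",
      sep = "")
  cat("  external: eta=", x$eta, " zeta=", x$zeta, "\n", sep = "")
  cat("  integrator: epsilon=", x$epsilon, " f_noise=", x$f_noise,
      " k_noise=", x$k_noise, "\n", sep = "")
  cat("  thresholds: l_min=", x$l_min, " A_min=", x$A_min,
      " lockout=", x$lockout, "\n", sep = "")
  invisible(x)
}
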