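#' Load a YAML configuration
#'
#' Reads a config with up to three sections — `params` (model
#' parameters, see [model_params()]), `protocol` (see
#' [protocol_config()]) and `region` (see [region_spec()]) — validates
#' it, fills defaults, and rejects unknown keys.
#'
#' @param path path to a YAML file.
#' @return list with elements `params`, `cfg`, `spec`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), c("params", "protocol", "region"))
  if (length(bad)) abort_cfg("unknown config section", bad[1])
  params <- do.call(model_params, as_plain_args(raw$params))
  cfg <- do.call(protocol_config, as_plain_args(raw$protocol))
  spec <- do.call(region_spec, as_plain_args(raw$region))
  list(params = params, cfg = cfg, spec = spec)
}

as_plain_args <- function(x) {
  if (is.null(x)) return(list())
  x <- lapply(x, function(v) if (is.list(v)) unlist(v) else v)
  x[!vapply(x, is.null, logical(1))]
}

#' Write a YAML configuration
#'
#' Inverse of [load_config()]; `load -> dump -> load` is idempotent.
#'
#' @param config list with `params`, `cfg`, `spec` (as returned by
#'   [load_config()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    x[lengths(x) > 0]
  }
  yaml::write_yaml(list(params = strip(config$params),
                        protocol = strip(config$cfg),
                        region = strip(config$spec)), path)
  invisible(path)
}

#' Save / load a tissue snapshot
#'
#' JSON round trip of the full state (positions at full double
#' precision, cycles, classes, domain, per-cell and per-junction
#' attributes). Loading re-validates the mesh.
#'
#' @param state a `corti_tissue`.
#' @param path file path.
#' @return `save_snapshot` returns `path` invisibly; `load_snapshot`
#'   returns the `corti_tissue`.
#' @export
save_snapshot <- function(state, path) {
  obj <- list(
    # positions as 17-significant-digit decimal strings: exact double
    # round trip, independent of the JSON writer's numeric formatting
    pos_chr = matrix(sprintf("%.17g", state$pos), ncol = 2),
    cells = unname(state$cells),
    class = state$class, alive = state$alive,
    domain = state$domain, y0 = state$y0, step = state$step,
    A0_scale = state$A0_scale, Gamma_scale = state$Gamma_scale,
    edge_keys = attr(state, "edge_keys"),
    edge_gamma_scale = state$edge_gamma_scale,
    lockout = ifelse(is.finite(state$lockout), state$lockout, -1e18),
    hc_cap = attr(state, "hc_cap"))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_snapshot
#' @export
load_snapshot <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pos <- matrix(as.numeric(obj$pos_chr), ncol = 2)
  cells <- if (is.matrix(obj$cells)) {
    lapply(seq_len(nrow(obj$cells)), function(i) as.integer(obj$cells[i, ]))
  } else lapply(obj$cells, as.integer)
  nv <- nrow(pos)
  refd <- unlist(cells)
  if (length(refd) && max(refd) > nv)
    abort_cfg("snapshot refers to a missing vertex")
  state <- new_tissue(pos, cells, obj$class,
                      domain = if (is.null(obj$domain)) NULL
                               else as.numeric(obj$domain),
                      y0 = obj$y0)
  state$alive <- as.logical(obj$alive)
  state$step <- as.integer(obj$step)
  state$A0_scale <- as.numeric(obj$A0_scale)
  state$Gamma_scale <- as.numeric(obj$Gamma_scale)
  state <- rebuild_topology(state)
  m <- match(attr(state, "edge_keys"), obj$edge_keys)
  hit <- !is.na(m)
  state$edge_gamma_scale[hit] <- obj$edge_gamma_scale[m[hit]]
  lk <- obj$lockout[m[hit]]
  lk[lk <= -1e17] <- -Inf
  state$lockout[hit] <- lk
  if (!is.null(obj$hc_cap)) attr(state, "hc_cap") <- obj$hc_cap
  audit_tissue(state)
  state
}

#' Write / read an event log as TSV
#' @param events event tibble (or a `corti_trajectory`).
#' @param path file path.
#' @return `path` invisibly / the event tibble.
#' @export
write_events <- function(events, path) {
  if (inherits(events, "corti_trajectory")) events <- events$events
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      colClasses = c("integer", "character",
                                                     "character", "numeric",
                                                     "numeric")))
}

#' Write / read a centroid table as CSV
#' @param pts centroid tibble (or a `corti_tissue`).
#' @param path file path.
#' @return `path` invisibly / the centroid tibble.
#' @export
write_centroids <- function(pts, path) {
  if (inherits(pts, "corti_tissue")) pts <- as_centroid_tibble(pts)
  utils::write.csv(pts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_centroids
#' @export
read_centroids <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Run manifest
#'
#' Writes the YAML manifest that fully determines a re-run: protocol
#' name, seed, config hash, effective parameters and step counts.
#'
#' @param path output path.
#' @param protocol protocol name.
#' @param seed integer seed.
#' @param params effective `corti_params`.
#' @param cfg effective `corti_protocol_config`.
#' @return `path` invisibly.
#' @export
write_manifest <- function(path, protocol, seed, params, cfg) {
  yaml::write_yaml(list(
    protocol = protocol, seed = seed,
    config_hash = rlang::hash(list(unclass(params), unclass(cfg))),
    package_version = as.character(utils::packageVersion("cortivertex")),
    params = unclass(params), protocol_config = unclass(cfg)), path)
  invisible(path)
}

#' Canonical test and demonstration fixtures
#'
#' Deterministic small objects used across the documentation and tests:
#' \describe{
#'   \item{`hex`}{a regular hexagonal lattice (`region_spec` arguments).}
#'   \item{`checkerboard_strip`}{a square-cell torus mesh with a pillar
#'     row, three alternating HC/SC rows, a top-boundary row and outside
#'     cells — the idealized final pattern, where every middle-row hair
#'     cell has exactly four supporting-cell neighbors.}
#'   \item{`pinwheel`}{a hexagonal lattice with one junction shrunk below
#'     the T1 threshold.}
#'   \item{`stretched_hexagon`}{a centroid table: a hair cell and its six
#'     neighbors on a regular hexagon stretched by `r` along x.}
#'   \item{`spiral_arc`}{a centroid table of equally arc-spaced points on
#'     a circle, for the straightening routine.}
#' }
#'
#' @param kind one of the fixture names above.
#' @param ... kind-specific options (`rows`, `cols`, `r`, `n`, `radius`,
#'   `spacing`).
#' @return a `corti_tissue` or a centroid tibble, per kind.
#' @export
make_fixture <- function(kind = c("hex", "checkerboard_strip", "pinwheel",
                                  "stretched_hexagon", "spiral_arc"), ...) {
  kind <- match.arg(kind)
  opts <- list(...)
  switch(kind,
    hex = hexagonal_lattice(do.call(region_spec, opts)),
    checkerboard_strip = {
      R <- opts$rows %||% 7L; C <- opts$cols %||% 8L
      square_torus_mesh(R, C)
    },
    pinwheel = {
      state <- hexagonal_lattice(region_spec(
        rows = 4, cols = 4, outside_bottom = 1, ihc_rows = 1,
        pillar_rows = 1, ohc_rows = 1, outside_top = 0))
      state$class[] <- "SC"
      ed <- tissue_edges(state)
      e <- 1L
      a <- ed[e, "v1"]; b <- ed[e, "v2"]
      d <- min_image2(rbind(state$pos[b, ] - state$pos[a, ]),
                      state$domain)[1, ]
      m <- state$pos[a, ] + d / 2
      u <- d / sqrt(sum(d^2))
      state$pos[a, ] <- m - u * 0.025
      state$pos[b, ] <- m + u * 0.025
      attr(state, "short_edge") <- e
      state
    },
    stretched_hexagon = {
      r <- opts$r %||% 1.5
      ang <- (0:5) * pi / 3
      tibble::tibble(
        id = 1:7, class = "HC",
        x = c(0, r * cos(ang)), y = c(0, sin(ang)),
        row = c("OHC2", "OHC2", "OHC3", "OHC3", "OHC2", "OHC1", "OHC1"))
    },
    spiral_arc = {
      n <- opts$n %||% 25; radius <- opts$radius %||% 20
      spacing <- opts$spacing %||% 2
      th <- (seq_len(n) - 1) * spacing / radius
      tibble::tibble(id = seq_len(n), class = "HC",
                     x = radius * sin(th), y = radius * (1 - cos(th)),
                     row = "OHC2")
    })
}

# Square-cell torus mesh whose middle three rows form a perfect
# checkerboard strip between a pillar row and the top boundary.
square_torus_mesh <- function(R, C) {
  vid <- function(i, j) (j %% R) * C + (i %% C) + 1L
  pos <- cbind(rep(0:(C - 1), times = R), rep(0:(R - 1), each = C))
  cells <- vector("list", R * C)
  cls <- character(R * C)
  for (j in 0:(R - 1)) for (i in 0:(C - 1)) {
    ci <- j * C + i + 1L
    cells[[ci]] <- c(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1),
                     vid(i, j + 1))
    cls[ci] <- if (j == 0) "pillar"
      else if (j <= 3) { if ((i + j) %% 2 == 0) "HC" else "SC" }
      else if (j == 4) "top_boundary" else "outside"
  }
  st <- new_tissue(pos * 1.0, cells, cls, domain = c(C, R), y0 = 1)
  st
}
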