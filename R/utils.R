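# Internal helpers shared across the package.

# Wrap coordinates into [0, L). L may be NULL (planar, no wrap).
wrap_coord <- function(x, L) {
  if (is.null(L) || !is.finite(L)) return(x)
  x - L * floor(x / L)
}

# Minimum-image displacement on a periodic axis of length L.
min_image <- function(d, L) {
  if (is.null(L) || !is.finite(L)) return(d)
  d - L * round(d / L)
}

# Minimum-image for an n x 2 displacement matrix given domain c(Lx, Ly) or NULL.
min_image2 <- function(d, domain) {
  if (is.null(domain)) return(d)
  d[, 1] <- min_image(d[, 1], domain[[1]])
  d[, 2] <- min_image(d[, 2], domain[[2]])
  d
}

wrap2 <- function(p, domain) {
  if (is.null(domain)) return(p)
  p[, 1] <- wrap_coord(p[, 1], domain[[1]])
  p[, 2] <- wrap_coord(p[, 2], domain[[2]])
  p
}

# Stable undirected edge key from two vertex ids (integer-packed; vertex
# ids stay far below 2^15 at the lattice sizes this model uses).
edge_key <- function(a, b) {
  pmin(a, b) * 32768 + pmax(a, b)
}

# rowsum() that returns a vector indexed 1..n even for absent groups.
rowsum_full <- function(x, group, n) {
  out <- numeric(n)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_cfg <- function(msg, key = NULL) {
  if (!is.null(key)) msg <- paste0(msg, " [key: ", key, "]")
  stop(structure(class = c("cortivertex_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

abort_topology <- function(msg) {
  stop(structure(class = c("cortivertex_topology_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
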