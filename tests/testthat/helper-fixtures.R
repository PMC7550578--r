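# Shared fixtures and small oracles used across the test files.

# A single planar polygonal cell (boundary edges allowed off the torus).
single_cell <- function(xy, class = "SC") {
  new_tissue(as.matrix(xy), list(seq_len(nrow(xy))), class)
}

unit_square_cell <- function(class = "SC") {
  single_cell(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), class)
}

regular_hexagon_cell <- function(side = 1, class = "SC") {
  ang <- pi / 6 + (0:5) * pi / 3
  single_cell(cbind(side * cos(ang), side * sin(ang)), class)
}

# A small disordered periodic lattice with randomized positions/classes,
# used for gradient and invariance checks.
random_lattice <- function(seed, rows = 4, cols = 4, jitter = 0.1,
                           classes = c("HC", "SC")) {
  set.seed(seed)
  st <- hexagonal_lattice(region_spec(
    rows = rows, cols = cols, outside_bottom = 1, ihc_rows = 1,
    pillar_rows = 1, ohc_rows = rows - 3, outside_top = 0))
  st$pos <- st$pos + matrix(stats::rnorm(length(st$pos), 0, jitter), ncol = 2)
  st$class <- sample(classes, length(st$class), replace = TRUE)
  st
}

# Independent finite-difference force oracle (central differences).
fd_gradient <- function(state, params, h = 1e-6, vertices = NULL) {
  if (is.null(vertices)) vertices <- seq_len(nrow(state$pos))
  G <- matrix(0, nrow(state$pos), 2)
  for (i in vertices) for (d in 1:2) {
    sp <- state; sp$pos[i, d] <- sp$pos[i, d] + h
    sm <- state; sm$pos[i, d] <- sm$pos[i, d] - h
    G[i, d] <- -(total_energy(sp, params) - total_energy(sm, params)) / (2 * h)
  }
  G
}

# Fan-triangulation polygon area oracle.
fan_area <- function(xy) {
  a <- 0
  for (i in 2:(nrow(xy) - 1)) {
    v1 <- xy[i, ] - xy[1, ]; v2 <- xy[i + 1, ] - xy[1, ]
    a <- a + (v1[1] * v2[2] - v1[2] * v2[1]) / 2
  }
  abs(a)
}

# Parameters with only the selected energy terms active.
bare_params <- function(...) {
  model_params(gamma_default = 0, gamma = c("pillar:*" = 0),
               Gamma = c(HC = 0, SC = 0, pillar = 0, IHC = 0,
                         top_boundary = 0, outside = 0),
               sigma = 0, eta = 0, zeta = 0, f_noise = 0, ...)
}

# Session-level cache for expensive shared simulation fixtures.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}
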