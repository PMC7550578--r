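hexagon_pts <- function(r = 1, rot = 0, stretch_x = 1) {
  ang <- (0:5) * pi / 3 + rot
  cbind(stretch_x * r * cos(ang), r * sin(ang))
}

test_that("psi6 equals one on a regular hexagon and is rotation invariant", {
  expect_equal(psi6(c(0, 0), hexagon_pts()), 1)
  for (rot in c(0.3, 1.1, 2.9))
    expect_equal(psi6(c(0, 0), hexagon_pts(rot = rot)), 1)
  # shifted center
  expect_equal(psi6(c(2, -1), sweep(hexagon_pts(), 2, c(-2, 1), "-")), 1)
})

test_that("psi6 matches direct summation on a perturbed angle set", {
  ang <- c(0, 60, 120, 180, 240, 330) * pi / 180
  pts <- cbind(cos(ang), sin(ang))
  # |(5 + exp(6i * 330 deg)) / 6| = |5 - 1| / 6 = 2/3
  expect_equal(psi6(c(0, 0), pts), 2 / 3, tolerance = 1e-12)
})

test_that("psi6 stays in [0, 1] and rejects coincident points", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(3:9, 1)
    pts <- matrix(stats::rnorm(2 * n), ncol = 2)
    v <- psi6(c(0, 0), pts)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_error(psi6(c(1, 2), rbind(c(1, 2), c(0, 0))),
               class = "cortivertex_config_error")
})

test_that("Voronoi adjacency matches an independent tessellation oracle", {
  # frozen cross-check: adjacency of 20 uniform points, computed once
  # with an independent computational-geometry library
  set.seed(42)
  xy <- matrix(round(stats::runif(40), 6), ncol = 2)
  expected <- rbind(
    c(1,4),c(1,12),c(1,16),c(2,5),c(2,7),c(2,13),c(2,17),c(3,4),c(3,8),
    c(3,11),c(3,14),c(3,19),c(4,10),c(4,12),c(4,19),c(5,6),c(5,7),c(5,9),
    c(5,15),c(5,17),c(6,9),c(6,11),c(6,14),c(6,15),c(6,18),c(6,20),c(7,9),
    c(7,12),c(7,13),c(8,14),c(8,18),c(9,12),c(9,20),c(10,11),c(10,12),
    c(10,19),c(11,12),c(11,14),c(11,19),c(11,20),c(12,13),c(12,16),
    c(12,20),c(13,16),c(13,17),c(14,18),c(15,17),c(15,18),c(16,17))
  va <- cortivertex:::voronoi_adjacency(xy)
  got <- cbind(pmin(va$pairs[, 1], va$pairs[, 2]),
               pmax(va$pairs[, 1], va$pairs[, 2]))
  got <- got[order(got[, 1], got[, 2]), ]
  expect_equal(unname(got), unname(expected))
})

test_that("Voronoi neighbor graph: triangle, square grid, symmetry", {
  tri <- tibble::tibble(id = 1:3, class = "HC",
                        x = c(0, 1, 0.4), y = c(0, 0, 1))
  gr <- hc_neighbor_graph(tri)
  expect_equal(gr$adjacency[["1"]], c(2L, 3L))
  expect_equal(gr$adjacency[["2"]], c(1L, 3L))
  expect_true(all(gr$boundary))

  grid <- expand.grid(x = 0:4, y = 0:4)
  pts <- tibble::tibble(id = seq_len(25), class = "HC",
                        x = grid$x, y = grid$y)
  gr2 <- hc_neighbor_graph(pts)
  center <- pts$id[pts$x == 2 & pts$y == 2]
  nb <- gr2$adjacency[[as.character(center)]]
  expect_length(nb, 4)   # rook neighbors only: corner contacts excluded
  expect_setequal(nb, pts$id[abs(pts$x - 2) + abs(pts$y - 2) == 1])
  expect_false(gr2$boundary[as.character(center)])

  # symmetry of the relation
  for (i in names(gr2$adjacency)) {
    for (j in gr2$adjacency[[i]])
      expect_true(as.integer(i) %in% gr2$adjacency[[as.character(j)]])
  }
})

test_that("collinear point sets are rejected", {
  bad <- tibble::tibble(id = 1:4, class = "HC", x = 1:4, y = 2 * (1:4) + 1)
  expect_error(hc_neighbor_graph(bad), class = "cortivertex_config_error")
})

test_that("psi6_star inverts a known row-axis stretch", {
  for (r in c(1.2, 1.4, 1.6)) {
    pts <- make_fixture("stretched_hexagon", r = r)
    res <- psi6_star(pts, cells = 1L)
    expect_equal(res$psi6_star, 1, tolerance = 1e-6)
    expect_equal(res$r_e_fit, r, tolerance = 1e-6)
    expect_lt(res$psi6_raw, 1 - 1e-3)
  }
  # unstretched: fitted ratio 1 and psi* = psi6 = 1
  pts1 <- make_fixture("stretched_hexagon", r = 1)
  res1 <- psi6_star(pts1, cells = 1L)
  expect_equal(res1$r_e_fit, 1, tolerance = 1e-6)
  expect_equal(res1$psi6_star, 1, tolerance = 1e-8)
  expect_equal(res1$psi6_raw, 1, tolerance = 1e-8)
})

test_that("rescaling recovers order lost to anisotropy under jitter", {
  set.seed(31)
  base <- make_fixture("stretched_hexagon", r = 1.5)
  diffs <- replicate(400, {
    pts <- base
    jit <- matrix(stats::rnorm(14, 0, 0.02), ncol = 2)  # 2% of spacing
    pts$x <- pts$x + jit[, 1]; pts$y <- pts$y + jit[, 2]
    res <- psi6_star(pts, cells = 1L)
    c(star = res$psi6_star, raw = res$psi6_raw)
  })
  expect_gt(mean(diffs["star", ]), mean(diffs["raw", ]))
  expect_gt(mean(diffs["star", ]), 0.9)
})

test_that("SC-neighbor counts on the checkerboard strip are four", {
  st <- make_fixture("checkerboard_strip")
  nc <- sc_neighbor_count(st)
  mid <- nc[nc$row == "OHC2" & !nc$excluded, ]
  expect_true(nrow(mid) > 0)
  expect_true(all(mid$n_sc == 4))
  # complementary identity on every hair cell
  expect_equal(nc$n_sc + nc$n_hc +
                 (nc$n_neighbors - nc$n_sc - nc$n_hc), nc$n_neighbors)
  hex <- hexagonal_lattice(region_spec())
  hex$class[] <- "SC"; hex$class[40] <- "HC"
  nc2 <- sc_neighbor_count(hex)
  expect_equal(nc2$n_sc, 6)
})

test_that("area ratio averages HC/SC pairs with hand-checked values", {
  st <- make_fixture("checkerboard_strip")
  expect_equal(area_ratio(st), 1)   # all unit squares

  # column of HCs (area 2) flanked by SC columns of areas 1 and 3:
  # every (HC, adjacent SC) pair contributes, mean(2/1, 2/3)
  vid <- function(i, j, C = 4, R = 3) (j %% R) * C + (i %% C) + 1L
  xs <- c(0, 2, 3, 5)  # column widths 2, 1, 2, 3 on a torus of length 8
  pos <- cbind(rep(xs, 3), rep(c(0, 1, 2), each = 4))
  cells <- list(); cls <- character(12)
  for (j in 0:2) for (i in 0:3) {
    ci <- j * 4 + i + 1
    cells[[ci]] <- c(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1),
                     vid(i, j + 1))
    cls[ci] <- if (i == 0) "HC" else "SC"
  }
  st2 <- new_tissue(pos, cells, cls, domain = c(8, 3), y0 = 0)
  g <- tissue_geometry(st2)
  expect_equal(g$area[1:4], c(2, 1, 2, 3))
  expect_equal(area_ratio(st2), mean(c(2 / 1, 2 / 3)))

  # homogeneity: doubling every HC area doubles the mean ratio
  pairs <- area_ratio(st2, pairs = TRUE)
  expect_equal(mean(2 * pairs$ratio), 2 * area_ratio(st2))
})

test_that("row classification labels borders and counts bands", {
  st <- make_fixture("checkerboard_strip")
  cr <- classify_rows(st)
  hc <- cr$pts[cr$pts$class == "HC", ]
  expect_equal(cr$n_rows, 3)
  expect_true(all(hc$row[hc$y < 1.5] == "OHC1"))
  expect_true(all(hc$row[hc$y > 2.5] == "OHC3"))
  expect_true(all(hc$row[hc$y > 1.5 & hc$y < 2.5] == "OHC2"))
  expect_equal(sum(hc$row == "OHC1"), 4)
  expect_equal(sum(hc$row == "OHC2"), 4)
  expect_equal(sum(hc$row == "OHC3"), 4)

  # a single row of centroids: every cell is OHC1, one band
  single <- tibble::tibble(id = 1:6, class = "HC",
                           x = seq(0, 10, length.out = 6),
                           y = stats::rnorm(6, 0, 0.01))
  cr1 <- classify_rows(single)
  expect_equal(cr1$n_rows, 1)
  expect_true(all(cr1$pts$row == "OHC1"))
})

test_that("straightening aligns an arc with the x-axis isometrically", {
  pts <- make_fixture("spiral_arc", n = 25, radius = 20, spacing = 2)
  # consecutive spacings before
  d0 <- sqrt(diff(pts$x)^2 + diff(pts$y)^2)
  out <- straighten_centroids(pts, backbone = pts$id)
  d1 <- sqrt(diff(out$x)^2 + diff(out$y)^2)
  expect_equal(d1, d0, tolerance = 1e-9)
  len <- max(out$x) - min(out$x)
  # the first pivot absorbs the initial tilt estimate, so collinearity is
  # assessed over the straightened chain
  expect_lt(max(abs(out$y[-1] - mean(out$y[-1]))), 0.01 * len)

  # an already straight row passes through unchanged
  straight <- tibble::tibble(id = 1:12, class = "HC",
                             x = seq(0, 22, 2), y = 0, row = "OHC2")
  out2 <- straighten_centroids(straight)
  expect_equal(out2$x, straight$x, tolerance = 1e-10)
  expect_equal(out2$y, straight$y, tolerance = 1e-10)
})

test_that("structure factor has exact zero-q limit and Bragg peaks", {
  set.seed(77)
  pts <- tibble::tibble(id = 1:40, class = "HC",
                        x = stats::runif(40, 0, 10),
                        y = stats::runif(40, 0, 10))
  sf <- structure_factor(pts, q_max = 3, n_q = 21)
  expect_equal(sf$S[sf$qx == 0 & sf$qy == 0], 40)
  expect_true(all(abs(Im(sf$S)) < 1e-10))

  # rectangular lattice: S = N at the first reciprocal vector
  a <- 1.7
  lat <- expand.grid(x = a * (0:5), y = 2.1 * (0:4))
  sfl <- structure_factor(tibble::tibble(id = seq_len(30), class = "HC",
                                         x = lat$x, y = lat$y),
                          q_max = 2 * pi / a, n_q = 3)
  bragg <- sfl$S[abs(sfl$qx - 2 * pi / a) < 1e-9 & sfl$qy == 0]
  expect_equal(bragg, 30, tolerance = 1e-8)

  # Poisson points: mean S over nonzero q is ~1
  set.seed(123)
  pp <- tibble::tibble(id = 1:200, class = "HC",
                       x = stats::runif(200, 0, 50),
                       y = stats::runif(200, 0, 50))
  sfp <- structure_factor(pp, q_max = 3, n_q = 15)
  nz <- sfp$S[!(sfp$qx == 0 & sfp$qy == 0) &
                sqrt(sfp$qx^2 + sfp$qy^2) > 0.5]
  se <- stats::sd(nz) / sqrt(length(nz))
  expect_lt(abs(mean(nz) - 1), 3 * se + 0.2)
})

test_that("event rates divide counts by region size and duration", {
  ev <- tibble::tibble(step = c(1, 5, 9, 12, 20, 30),
                       kind = rep("T1", 6),
                       cells = as.character(1:6), x = 0, y = 0)
  expect_equal(count_events(ev, "T1", n_cells = 30, duration = 2), 0.1)
  empty <- ev[0, ]
  expect_equal(count_events(empty, "T1", n_cells = 30, duration = 2), 0)
  expect_equal(count_events(ev, "T2", n_cells = 30, duration = 2), 0)
})

test_that("displacement profiles vanish for static and rigidly drifting tissue", {
  st <- make_fixture("checkerboard_strip")
  mk_traj <- function(snaps)
    cortivertex:::new_trajectory(snaps, tibble::tibble(), NULL,
                                 snaps[[length(snaps)]], model_params(),
                                 "test")
  s2 <- st; s2$step <- 10L
  static <- displacement_profiles(mk_traj(list(st, s2)))
  expect_true(all(abs(static$mean_dx) < 1e-12))
  expect_true(all(abs(static$mean_dy) < 1e-12))

  s3 <- st
  s3$pos <- wrap2(st$pos + matrix(c(1.3, 0.6), nrow(st$pos), 2, byrow = TRUE),
                  st$domain)
  s3$step <- 10L
  drift <- displacement_profiles(mk_traj(list(st, s3)))
  expect_true(all(abs(drift$mean_dx) < 1e-10))
  expect_true(all(abs(drift$mean_dy) < 1e-10))
})
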