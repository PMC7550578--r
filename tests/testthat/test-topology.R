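test_that("T1 swaps adjacency and conserves the mesh counts", {
  st <- make_fixture("pinwheel")
  e <- attr(st, "short_edge")
  ed <- tissue_edges(st)
  c1 <- ed[e, "c1"]; c2 <- ed[e, "c2"]
  p <- model_params(l_min = 0.1, l_new_factor = 1.6, lockout = 50)

  adj_pairs <- function(s) {
    a <- cortivertex:::cell_adjacency(s)
    paste(pmin(a[, 1], a[, 2]), pmax(a[, 1], a[, 2]))
  }
  before <- adj_pairs(st)
  deg_before <- table(factor(c(tissue_edges(st)[, "c1"],
                               tissue_edges(st)[, "c2"]),
                             levels = seq_along(st$cells)))

  res <- apply_t1(st, e, p)
  expect_true(res$applied)
  new <- res$state
  audit_tissue(new, check_simple = TRUE)

  # counts conserved
  expect_identical(tissue_counts(new), tissue_counts(st))

  after <- adj_pairs(new)
  key12 <- paste(min(c1, c2), max(c1, c2))
  expect_true(key12 %in% before)
  expect_false(key12 %in% after)
  da_db <- setdiff(res$cells, c(c1, c2))
  keydd <- paste(min(da_db), max(da_db))
  expect_false(keydd %in% before)
  expect_true(keydd %in% after)

  # neighbor counts: losers -1, gainers +1, total conserved
  deg_after <- table(factor(c(tissue_edges(new)[, "c1"],
                              tissue_edges(new)[, "c2"]),
                            levels = seq_along(st$cells)))
  expect_equal(sum(deg_after), sum(deg_before))
  expect_equal(as.integer(deg_after[c(c1, c2)]),
               as.integer(deg_before[c(c1, c2)]) - 1L)
  expect_equal(as.integer(deg_after[da_db]),
               as.integer(deg_before[da_db]) + 1L)

  # the re-extended junction is l_new long and perpendicular memory is
  # recorded through the lockout stamp
  a <- ed[e, "v1"]; b <- ed[e, "v2"]
  d <- new$pos[b, ] - new$pos[a, ]
  d <- d - new$domain * round(d / new$domain)
  expect_equal(sqrt(sum(d^2)), p$l_new_factor * p$l_min, tolerance = 1e-10)
})

test_that("T1 candidates honor threshold, lockout and the frozen boundary", {
  st <- make_fixture("pinwheel")
  e <- attr(st, "short_edge")
  p <- model_params(l_min = 0.1, lockout = 50)
  expect_identical(find_t1_candidates(st, p), e)

  long <- model_params(l_min = 0.01)
  expect_length(find_t1_candidates(st, long), 0)

  # within the lockout window a re-shrunk junction is not a candidate
  res <- apply_t1(st, e, p)
  new <- res$state
  ed <- tissue_edges(new)
  a <- tissue_edges(st)[e, "v1"]; b <- tissue_edges(st)[e, "v2"]
  enew <- which((ed[, "v1"] == min(a, b)) & (ed[, "v2"] == max(a, b)) |
                  (ed[, "v1"] == max(a, b)) & (ed[, "v2"] == min(a, b)))
  m <- (new$pos[a, ] + new$pos[b, ]) / 2
  new$pos[a, ] <- m + c(0.01, 0)
  new$pos[b, ] <- m - c(0.01, 0)
  expect_false(enew %in% find_t1_candidates(new, p))
  later <- new; later$step <- later$step + p$lockout + 1L
  expect_true(enew %in% find_t1_candidates(later, p))

  # junctions on the pillar/IHC rows are never candidates
  lat <- hexagonal_lattice(region_spec())
  lat <- assign_regions(lat, region_spec())
  pe <- which(cortivertex:::pillar_edge(lat))
  shrunk <- lat
  ed2 <- tissue_edges(lat)
  a2 <- ed2[pe[1], "v1"]; b2 <- ed2[pe[1], "v2"]
  m2 <- (shrunk$pos[a2, ] + shrunk$pos[b2, ]) / 2
  shrunk$pos[a2, ] <- m2 + c(0.01, 0)
  shrunk$pos[b2, ] <- m2 - c(0.01, 0)
  expect_false(pe[1] %in% find_t1_candidates(shrunk, p))
})

test_that("repeated T1 detection within the lockout yields one event only", {
  st <- make_fixture("pinwheel")
  p <- model_params(l_min = 0.1, lockout = 50, l_new_factor = 1.05)
  # with l_new barely above l_min, noise-free relaxation could re-shrink
  # the junction; the lockout must prevent an immediate second flip
  r1 <- cortivertex:::topology_step(st, p)
  expect_identical(r1$event$kind, "T1")
  r2 <- cortivertex:::topology_step(r1$state, p)
  if (!is.null(r2$event)) expect_false(identical(r2$event, r1$event))
})

test_that("T2 removes a triangle with exact Euler bookkeeping", {
  st <- hexagonal_lattice(region_spec(
    rows = 6, cols = 6, outside_bottom = 2, ihc_rows = 1, pillar_rows = 1,
    ohc_rows = 1, outside_top = 1))
  st$class[] <- "SC"
  p <- model_params(l_min = 0.05, A_min = 0.1)
  target <- 15L
  # shrink the cell to a triangle through forced intercalations
  while (length(st$cells[[target]]) > 3L) {
    res <- cortivertex:::forced_t1(st, target, p, max_tries = 6L)
    expect_false(is.null(res))
    st <- res$state
  }
  cnt0 <- tissue_counts(st)
  ad <- cortivertex:::cell_adjacency(st)
  nbs <- setdiff(unique(c(ad[ad[, 1] == target, 2],
                          ad[ad[, 2] == target, 1])), target)
  deg0 <- sapply(nbs, function(cc) sum(ad == cc))

  res <- apply_t2(st, target, p)
  expect_true(res$applied)
  new <- res$state
  audit_tissue(new, check_simple = TRUE)
  cnt1 <- tissue_counts(new)
  expect_equal(cnt1["cells"], cnt0["cells"] - 1L, ignore_attr = TRUE)
  expect_equal(cnt1["vertices"], cnt0["vertices"] - 2L, ignore_attr = TRUE)
  expect_equal(cnt1["junctions"], cnt0["junctions"] - 3L, ignore_attr = TRUE)
  expect_false(new$alive[target])

  # each neighbor lost exactly one junction
  ad1 <- cortivertex:::cell_adjacency(new)
  deg1 <- sapply(nbs, function(cc) sum(ad1 == cc))
  expect_equal(deg1, deg0 - 1L)

  # mechanics remain well-defined after removal
  pp <- model_params(sigma = 0.1, D = 1.5)
  expect_true(is.finite(total_energy(new, pp)))
  G <- energy_gradient(new, pp)
  vs <- sample(unique(cortivertex:::tissue_slots(new)$v), 4)
  Gfd <- fd_gradient(new, pp, vertices = vs)
  expect_lt(max(abs(G[vs, ] - Gfd[vs, ]) / pmax(abs(Gfd[vs, ]), 1)), 1e-5)
})

test_that("T2 candidates honor area threshold and class eligibility", {
  st <- make_fixture("checkerboard_strip", rows = 7, cols = 8)
  p <- model_params(A_min = 0.2)
  expect_length(find_t2_candidates(st, p), 0)

  shrink_cell <- function(s, cell, f = 0.3) {
    cyc <- s$cells[[cell]]
    ctr <- colMeans(s$pos[cyc, ])
    s$pos[cyc, ] <- sweep(sweep(s$pos[cyc, ], 2, ctr), 1, f, "*") +
      rep(ctr, each = length(cyc))
    s
  }
  sc <- which(st$class == "SC")[3]
  st2 <- shrink_cell(st, sc)
  expect_identical(find_t2_candidates(st2, p), sc)

  # a hair cell below threshold is ineligible unless explicitly allowed
  hc <- which(st2$class == "HC")[3]
  st3 <- shrink_cell(st2, hc)
  expect_false(hc %in% find_t2_candidates(st3, p))
  p_all <- model_params(A_min = 0.2, hc_t2_allowed = TRUE)
  expect_true(hc %in% find_t2_candidates(st3, p_all))
})

test_that("mesh invariants survive a long event-rich run", {
  set.seed(21)
  p <- model_params(sigma = 0.3, D = 2.0, eta = 0.05, zeta = -0.4,
                    f_noise = 0.08, l_min = 0.25, A_min = 0.3, lockout = 20)
  spec <- region_spec(rows = 8, cols = 6, outside_bottom = 1, ihc_rows = 1,
                      pillar_rows = 1, ohc_rows = 3, outside_top = 2)
  st <- init_tissue(spec, p, seed = 21, disorder_cycles = 5,
                    relax_steps = 50)
  tr <- advance(st, p, 400, record_every = 0, differentiate = TRUE,
                hc_cap = attr(st, "hc_cap"), collect_metrics = FALSE)
  expect_silent(audit_tissue(tr$final, check_simple = TRUE))
  # events happened and every T1 left the counts unchanged overall,
  # every T2 removed one cell
  n_t2 <- sum(tr$events$kind == "T2")
  cnt <- tissue_counts(tr$final)
  expect_equal(cnt[["cells"]], sum(st$alive) - n_t2)
  expect_equal(cnt[["vertices"]] - 2 * cnt[["cells"]], 0)
})
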