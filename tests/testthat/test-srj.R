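test_that("tile event counting deduplicates per sample per tile", {
  g <- genome_def("chr1", 2e6)
  b <- make_bins(g, 1e5)
  # one sample with 4 rearrangements in the same tile
  r <- make_rearrs(rep("chr1", 4), c(10, 20, 30, 40) + 1e5,
                   rep("chr1", 4), c(10, 20, 30, 40) + 9e5,
                   rep("sA", 4), genome = g)
  ev <- count_tile_events(r, b, min_event_size = 0)
  expect_equal(ev$observed, 1)
  # 3 samples, one rearrangement each, same tile
  r3 <- make_rearrs(rep("chr1", 3), rep(1e5 + 5, 3),
                    rep("chr1", 3), rep(9e5 + 5, 3), c("a", "b", "c"),
                    genome = g)
  expect_equal(count_tile_events(r3, b, 0)$observed, 3)
  # both ends in one bin -> diagonal tile
  rd <- make_rearrs("chr1", 1e5 + 10, "chr1", 1e5 + 5000, "sA", genome = g)
  evd <- count_tile_events(rd, b, 0)
  expect_equal(c(evd$i, evd$j), c(2, 2))
  # short events dropped by the size filter
  rs <- make_rearrs("chr1", 100, "chr1", 500, "sA", genome = g)
  expect_equal(nrow(count_tile_events(rs, b, 1000)), 0)
})

test_that("binomial tail matches brute-force summation", {
  expect_equal(binom_tail(2, 1000, 1e-4), 0.004670, tolerance = 2e-3)
  expect_equal(srj_test(0, 100, 0.01), 1)
  expect_error(srj_test(5, 100, 0), "positive")
  set.seed(7)
  for (i in 1:25) {
    n <- sample(10:2000, 1); p <- runif(1, 1e-5, 0.2)
    k <- sample(0:min(n, 30), 1)
    expect_equal(srj_test(k, n, p), binom_tail_brute(k, n, p),
                 tolerance = 1e-12)
  }
})

test_that("juxtaposition background is a normalized symmetric distribution", {
  cfg <- sim_config(seed = 2, n_samples = 100, rearr_per_sample = 5)
  sim <- simulate_rearrangements(cfg)
  counts <- count_breakpoints(sim$rearrs, sim$bins)
  bg <- fit_juxtaposition_background(sim$rearrs, counts, sim$bins)
  ut <- upper.tri(bg$p0, diag = TRUE)
  expect_equal(sum(bg$p0[ut]), 1, tolerance = 1e-9)
  expect_equal(bg$p0, t(bg$p0))
  # uniform rates and w = 1 give a uniform tile distribution
  bg1 <- fit_juxtaposition_background(sim$rearrs, rep(1, nrow(sim$bins)),
                                      sim$bins, w_grid = 1)
  vals <- bg1$p0[ut]
  expect_equal(max(vals[row(bg$p0)[ut] != col(bg$p0)[ut]]),
               min(vals[row(bg$p0)[ut] != col(bg$p0)[ut]]),
               tolerance = 1e-12)
  # errors on degenerate input
  expect_error(fit_juxtaposition_background(sim$rearrs,
                                            rep(0, nrow(sim$bins)),
                                            sim$bins), "all-zero")
})

test_that("kernel is non-increasing beyond the first distance bin", {
  cfg <- sim_config(seed = 3, n_samples = 200, rearr_per_sample = 10,
                    mixture_w = 0.2)
  sim <- simulate_rearrangements(cfg)
  counts <- count_breakpoints(sim$rearrs, sim$bins)
  bg <- fit_juxtaposition_background(sim$rearrs, counts, sim$bins)
  g <- bg$kernel$g[bg$kernel$tiles > 0]
  g <- g[-1]                     # drop the zero-distance (diagonal) class
  expect_true(all(diff(g) <= 1e-12))
})

test_that("mixture weight is recovered from simulated truth", {
  cfg <- sim_config(seed = 11, mixture_w = 0.3, n_samples = 250,
                    rearr_per_sample = 20)   # ~5,000 rearrangements
  sim <- simulate_rearrangements(cfg)
  counts <- count_breakpoints(sim$rearrs, sim$bins)
  bg <- fit_juxtaposition_background(sim$rearrs, counts, sim$bins)
  expect_lte(abs(bg$w - 0.3), 0.1)
})

test_that("effect size is the observed/expected ratio", {
  expect_equal(effect_size(4, 2), 2)
  expect_equal(effect_size(3, 3), 1)
  expect_equal(effect_size(4 * 7, 2 * 7), effect_size(4, 2))
  expect_error(effect_size(1, 0), "positive")
})

test_that("robustness factor brackets the significance boundary", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(500:5000, 1)
    p0 <- runif(1, 1e-6, 1e-4)
    obs <- sample(3:10, 1)
    alpha <- 1e-3
    if (binom_tail(obs, n, p0) > alpha) next
    r <- robustness_factor(obs, n, p0, alpha)
    expect_gte(r, 1)
    expect_lte(binom_tail(obs, n, min(1, r * 0.99 * p0)), alpha)
    expect_gt(binom_tail(obs, n, min(1, r * 1.01 * p0)), alpha)
  }
  # not significant -> missing
  expect_true(is.na(robustness_factor(1, 100, 0.05, 1e-4)))
})

test_that("permuting sample labels leaves SRJ statistics unchanged", {
  cfg <- sim_config(seed = 17, n_samples = 80, rearr_per_sample = 5)
  sim <- simulate_rearrangements(cfg)
  res1 <- srj_scan(sim$rearrs, sim$bins)
  r2 <- sim$rearrs
  perm <- sample(unique(r2$sample))
  names(perm) <- unique(r2$sample)
  r2$sample <- unname(perm[r2$sample])
  res2 <- srj_scan(r2, sim$bins)
  expect_equal(res1$tiles$p, res2$tiles$p)
  expect_equal(res1$tiles$q, res2$tiles$q)
})

test_that("a planted juxtaposition is detected with a valid robustness factor", {
  cfg <- sim_config(seed = 5, n_samples = 100, rearr_per_sample = 6,
                    srj_spikes = data.frame(bin_i = 120, bin_j = 470,
                                            frequency = 0.03))
  sim <- simulate_rearrangements(cfg)
  res <- srj_scan(sim$rearrs, sim$bins)
  top <- res$tiles[1, ]
  expect_equal(c(top$bin_i, top$bin_j), c(120, 470))
  expect_lt(top$q, 0.1)
  expect_gt(top$effect_size, 1)
  expect_gte(top$robustness_factor, 1)
})

test_that("BH over a universe with an analytic unit block matches the literal reference", {
  set.seed(23)
  p <- runif(40)^2
  m <- 100
  q_pkg <- svdriverscan:::bh_with_unit_block(p, m)
  q_ref <- bh_reference(c(p, rep(1, m - 40)))[1:40]
  expect_equal(q_pkg, q_ref)
})
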