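bins6 <- make_bins(tiny_genome(), 1e5)   # 10 + 5 bins

test_that("breakpoint counting deduplicates per sample per bin", {
  # one sample, 3 breakpoints in one bin (plus partners elsewhere)
  r <- make_rearrs(rep("chr1", 3), c(10, 20, 30),
                   rep("chr2", 3), c(1e5 + 1, 2e5 + 1, 3e5 + 1), rep("sA", 3))
  cnt <- count_breakpoints(r, bins6)
  expect_equal(cnt[1], 1)
  # 3 samples, 1 breakpoint each in the same bin
  r3 <- make_rearrs(rep("chr1", 3), c(10, 20, 30),
                    rep("chr2", 3), rep(1e5 + 1, 3), c("a", "b", "c"))
  expect_equal(count_breakpoints(r3, bins6)[1], 3)
  # DEL with both ends in one bin counts once for its sample
  rdel <- make_rearrs("chr1", 10, "chr1", 500, "sA", sv_class = "DEL")
  expect_equal(count_breakpoints(rdel, bins6)[1], 1)
  # empty input gives all zeros
  expect_equal(sum(count_breakpoints(make_rearrs(character(0), numeric(0),
    character(0), numeric(0), character(0)), bins6)), 0)
})

test_that("doubling every rearrangement leaves deduplicated counts unchanged", {
  set.seed(11)
  n <- 60
  r <- make_rearrs(rep("chr1", n), floor(runif(n) * 1e6),
                   rep("chr2", n), floor(runif(n) * 5e5),
                   sample(sprintf("s%d", 1:10), n, TRUE))
  doubled <- rearrangements(c(r$chrom1, r$chrom1), c(r$pos1, r$pos1),
                            c(r$chrom2, r$chrom2), c(r$pos2, r$pos2),
                            c(r$sample, r$sample), genome = tiny_genome())
  expect_equal(count_breakpoints(doubled, bins6),
               count_breakpoints(r, bins6))
})

test_that("Gamma-Poisson tail matches brute-force summation", {
  # Poisson limit worked value
  expect_equal(gp_tail(3, 1, 0), 0.0803014, tolerance = 1e-6)
  expect_equal(gp_tail(0, 5, 0.3), 1)
  set.seed(101)
  for (i in 1:25) {
    mu <- runif(1, 0.2, 30); alpha <- runif(1, 0.01, 1)
    k <- sample(0:40, 1)
    expect_equal(gp_tail(k, mu, alpha), nb_tail_brute(k, mu, alpha),
                 tolerance = 1e-10)
  }
})

test_that("background fit recovers simulated coefficients", {
  set.seed(21)
  n <- 10000
  g <- genome_def("chr1", n * 1e5)
  b <- make_bins(g, 1e5)
  x <- runif(n)
  # Poisson counts, log mu = 1 + 2 x + log(eligible) - log(1e5)
  # (fold the offset into the intercept scale via eligible = 1e5)
  mu <- exp(1 + 2 * x) / 1e5 * b$eligible
  y <- rpois(n, mu)
  fit <- fit_background(y, list(covariate_track("x", x)), b)
  expect_equal(unname(fit$coefficients["x"]), 2, tolerance = 0.05)
  expect_equal(unname(fit$coefficients["(Intercept)"]) + log(1e5), 1,
               tolerance = 0.05)
  expect_lt(fit$alpha, 0.02)

  # Gamma-Poisson with alpha = 0.5
  y2 <- rnbinom(n, mu = mu, size = 1 / 0.5)
  fit2 <- fit_background(y2, list(covariate_track("x", x)), b)
  expect_gt(fit2$alpha, 0.4)
  expect_lt(fit2$alpha, 0.6)
})

test_that("collinear covariates are rejected with names", {
  set.seed(3)
  n <- 200
  g <- genome_def("chr1", n * 1e5)
  b <- make_bins(g, 1e5)
  y <- rpois(n, 2)
  expect_error(
    fit_background(y, list(covariate_track("flat", rep(1, n))), b),
    "flat")
  x <- runif(n)
  expect_error(
    fit_background(y, list(covariate_track("a", x),
                           covariate_track("b", x * 3 + 1)), b),
    "collinear")
})

test_that("bins with low eligibility are excluded from fit and test", {
  set.seed(4)
  n <- 300
  g <- genome_def("chr1", n * 1e5)
  b <- make_bins(g, 1e5)
  b$eligible[1:10] <- 1e3          # below 10% of width
  y <- rpois(n, 3)
  fit <- fit_background(y, list(covariate_track("x", runif(n))), b)
  expect_false(any(fit$included[1:10]))
  p <- srb_pvalues(fit, y, b)
  expect_true(all(is.na(p[1:10])))
  expect_false(anyNA(p[11:n]))
  expect_true(all(p[11:n][y[11:n] == 0] == 1))
})

test_that("BH q-values match the literal step-up reference", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_error(benjamini_hochberg(c(0.1, NA)), "NA")
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(benjamini_hochberg(p), bh_reference(p))
  }
})

test_that("significant bins merge into maximal adjacent runs", {
  g <- genome_def("chr1", 1e6)
  b <- make_bins(g, 1e5)
  q <- rep(1, 10); p <- rep(1, 10)
  obs <- rep(2, 10); exp_ <- rep(1, 10)
  q[c(2, 3, 6, 9)] <- 0.01; p[c(2, 3, 6, 9)] <- 0.001
  loci <- merge_loci(b, obs, exp_, p, q, 0.1)
  expect_equal(nrow(loci), 3)
  expect_equal(loci$n_bins, c(2, 1, 1))
  expect_equal(loci$start[1], 1e5)
  expect_equal(loci$end[1], 3e5)
  expect_equal(loci$observed[1], 4)
  # adjacent rows on different chromosomes never merge
  b2 <- make_bins(tiny_genome(), 1e5)
  q2 <- rep(1, 15); q2[10:11] <- 0.01
  loci2 <- merge_loci(b2, rep(1, 15), rep(1, 15), rep(0.5, 15), q2, 0.1)
  expect_equal(nrow(loci2), 2)
})

test_that("dispersion score is normalized partner-bin entropy", {
  g <- genome_def("chr1", 2e6)
  b <- make_bins(g, 1e5)
  mk <- function(partner_bins) {
    n <- length(partner_bins)
    make_rearrs(rep("chr1", n), seq(10, 90, length.out = n),
                rep("chr1", n), (partner_bins - 1) * 1e5 + 50,
                sprintf("s%d", 1:n), genome = g)
  }
  expect_equal(dispersion_score(1, mk(rep(15, 8)), b), 0)
  expect_equal(dispersion_score(1, mk(5:12), b), 1)
  expect_equal(dispersion_score(1, mk(c(rep(5, 4), rep(9, 4))), b),
               log(2) / log(8))
  expect_true(is.na(dispersion_score(1, mk(7), b)))
})

test_that("SRB classification follows the decision tree", {
  expect_equal(classify_srb(0.1, 0.9, 2), "fusion-like")
  expect_equal(classify_srb(0.8, 0.6, 0), "fragile-like")
  expect_equal(classify_srb(0.8, 0.3, 1.4), "amplification")
  expect_equal(classify_srb(0.8, 0.3, -0.9), "deletion")
  expect_equal(classify_srb(0.8, 0.3, 0.05), "copy-neutral")
  expect_equal(classify_srb(0.8, NA, 1), "unclassified-fragility")
})

test_that("srb_scan recovers a planted recurrent locus end to end", {
  cfg <- sim_config(seed = 33, n_samples = 200, rearr_per_sample = 6,
                    srb_spikes = data.frame(bin = c(50, 400), fold = 5,
                                            regime = c("clustered",
                                                       "dispersed")))
  sim <- simulate_rearrangements(cfg)
  res <- srb_scan(sim$rearrs, sim$bins, sim$covariates,
                  rep_timing = sim$covariates$timing)
  hit_bins <- unlist(res$loci$bin_idx)
  expect_true(all(c(50, 400) %in% hit_bins))
  # the clustered locus is fusion-like, the dispersed one is not
  cls <- res$loci$class[vapply(res$loci$bin_idx, function(i) 50 %in% i, TRUE)]
  expect_equal(cls, "fusion-like")
})
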