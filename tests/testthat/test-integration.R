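test_that("Brown's combination reduces to the right special cases", {
  # single method: identity
  expect_equal(brown_combine(0.03), 0.03)
  expect_equal(brown_combine(c(NA, 0.03, NA)), 0.03)
  # two independent methods: Fisher's method, worked value
  expect_equal(brown_combine(c(0.05, 0.05)), 0.01747, tolerance = 1e-3)
  expect_equal(brown_combine(c(0.05, 0.05),
                             covariance = matrix(0, 2, 2)),
               pchisq(-2 * (log(0.05) + log(0.05)), df = 4,
                      lower.tail = FALSE))
  # two perfectly duplicated methods: cov(-2 ln p) = 4, combined equals
  # the single-method p
  cv <- matrix(4, 2, 2)
  for (p in c(0.5, 0.05, 1e-4))
    expect_equal(brown_combine(c(p, p), cv), p, tolerance = 1e-6)
  # p <= 0 clamped with warning
  expect_warning(res <- brown_combine(c(0, 0.5)), "clamped")
  expect_true(res > 0 && res < 1)
})

test_that("Brown equals Fisher exactly when covariance is forced to zero", {
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    p <- runif(k)
    fisher <- pchisq(sum(-2 * log(p)), df = 2 * k, lower.tail = FALSE)
    expect_equal(brown_combine(p, matrix(0, k, k)), fisher)
  }
})

test_that("combined p is uniform under correlated nulls", {
  # Gaussian-copula nulls at several correlations; empirical covariance
  set.seed(41)
  for (rho in c(0, 0.5, 0.9)) {
    cfg <- sim_config(seed = 100 + round(100 * rho), n_rows = 800,
                      n_methods = 5, rho = rho)
    ps <- simulate_pvalue_matrix(cfg)
    comb <- combine_matrix(ps$pmat)
    ks <- suppressWarnings(stats::ks.test(comb$p_combined, "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("method calibration keeps uniform methods and drops distorted ones", {
  set.seed(51)
  n <- 1000
  pm <- pvalue_matrix(
    cohort = rep("c1", 3 * n),
    element = rep(sprintf("e%04d", 1:n), 3),
    method = rep(c("good", "inflated", "sparse"), each = n),
    p = c(runif(n), runif(n)^2, runif(n)))
  # make "sparse" 90% missing by rebuilding
  keep <- c(rep(TRUE, 2 * n), runif(n) < 0.1)
  pm <- pvalue_matrix(rep("c1", 3 * n)[keep],
                      rep(sprintf("e%04d", 1:n), 3)[keep],
                      rep(c("good", "inflated", "sparse"), each = n)[keep],
                      c(runif(n), runif(n)^2, runif(n))[keep])
  cal <- calibrate_methods(pm)
  expect_true(cal$keep[cal$method == "good"])
  expect_false(cal$keep[cal$method == "inflated"])
  # analytic check: for p = U^2, -2 ln p = -4 ln U, lambda = 2
  expect_equal(cal$lambda[cal$method == "inflated"], 2, tolerance = 0.25)
  expect_true(cal$low_coverage[cal$method == "sparse"])
  expect_false(cal$low_coverage[cal$method == "good"])
  # all methods dropped is an error
  pm_bad <- pvalue_matrix(rep("c1", n), sprintf("e%04d", 1:n),
                          rep("only", n), runif(n)^3)
  expect_error(calibrate_methods(pm_bad), "calibration")
})

test_that("concatenated FDR assigns the quoted tiers", {
  df <- data.frame(p_combined = c(1e-6, 0.002, 0.2, 0.9))
  out <- concat_fdr(df)
  expect_equal(out$tier[out$q < 0.1][1], "significant")
  expect_true(all(out$tier[out$q >= 0.1 & out$q < 0.25] == "near"))
  expect_true(all(out$tier[out$q >= 0.25] == "ns"))
  # concatenating a second cohort changes m and hence q
  df2 <- data.frame(p_combined = c(df$p_combined, runif(10, 0.3, 1)))
  out2 <- concat_fdr(df2)
  expect_false(isTRUE(all.equal(out$q, out2$q[1:4])))
})

make_muts <- function(n, n_pat = n, mappable = 1, palindrome = 0,
                      apobec = 0, aid = 0, uv = 0) {
  sig <- function(f, on = 0.9, off = 0.02) {
    k <- round(f * n)
    c(rep(on, k), rep(off, n - k))
  }
  other <- pmax(0, 1 - (sig(apobec) + sig(aid) + sig(uv)))
  df <- data.frame(
    chrom = "chr1", pos = seq_len(n), ref = "A", alt = "T",
    sample = sprintf("s%d", rep_len(seq_len(n_pat), n)),
    in_mappable = rep_len(c(rep(TRUE, round(mappable * n)),
                            rep(FALSE, n - round(mappable * n))), n),
    in_palindrome = rep_len(c(rep(TRUE, round(palindrome * n)),
                              rep(FALSE, n - round(palindrome * n))), n),
    sig_apobec = sig(apobec), sig_aid = sig(aid), sig_uv = sig(uv),
    sig_other = other, stringsAsFactors = FALSE)
  svdriverscan:::annotate_mutations(df)
}

test_that("each post-filter fails on its own rule", {
  # passing candidate
  f <- apply_filters(make_muts(10), "other")
  expect_true(attr(f, "pass"))
  # counts and patients
  expect_false(attr(apply_filters(make_muts(2), "other"), "pass"))
  expect_false(attr(apply_filters(make_muts(6, n_pat = 2), "other"), "pass"))
  # mappability (> 0.5 required)
  expect_false(attr(apply_filters(make_muts(10, mappable = 0.5), "other"),
                    "pass"))
  # palindrome fraction >= 0.5 fails
  expect_false(attr(apply_filters(make_muts(10, palindrome = 0.6), "other"),
                    "pass"))
  # APOBEC >= 0.5 fails
  expect_false(attr(apply_filters(make_muts(10, apobec = 0.6), "other"),
                    "pass"))
  # AID 0.40: fails only in lymphoid
  expect_false(attr(apply_filters(make_muts(10, aid = 0.4), "lymphoid"),
                    "pass"))
  expect_true(attr(apply_filters(make_muts(10, aid = 0.4), "other"),
                   "pass"))
  # UV 0.6: fails only in melanoma
  expect_false(attr(apply_filters(make_muts(10, uv = 0.6), "melanoma"),
                    "pass"))
  expect_true(attr(apply_filters(make_muts(10, uv = 0.6), "other"),
                   "pass"))
  # missing annotations: not evaluable, flagged, but not failing
  bare <- data.frame(chrom = "chr1", pos = 1:5, ref = "A", alt = "T",
                     sample = sprintf("s%d", 1:5))
  fb <- apply_filters(svdriverscan:::annotate_mutations(bare), "other")
  expect_true(attr(fb, "pass"))
  expect_false(attr(fb, "evaluable"))
})

test_that("fraction filters are invariant to duplicating the mutation list", {
  m <- make_muts(9, apobec = 0.3, palindrome = 0.2)
  f1 <- apply_filters(m, "other")
  f2 <- apply_filters(rbind(m, m), "other")
  frac_rows <- f1$filter %in% c("mappable_frac", "palindrome_frac",
                                "apobec_frac", "aid_frac", "uv_frac")
  expect_equal(f1$value[frac_rows], f2$value[frac_rows])
})

test_that("filtering is idempotent and re-FDR matches BH on survivors", {
  cfg <- sim_config(seed = 61, n_rows = 300, n_methods = 4, rho = 0.2,
                    n_driver_rows = 10)
  ps <- simulate_pvalue_matrix(cfg)
  muts <- list()
  keys <- paste(ps$pmat$cohort, ps$pmat$element, sep = ":")
  for (k in keys) muts[[k]] <- make_muts(8)
  # poison a couple of known driver rows so filters remove them
  muts[[ps$truth[1]]] <- make_muts(8, apobec = 0.7)
  muts[[ps$truth[2]]] <- make_muts(2)
  led <- candidate_ledger(ps$pmat, muts)
  surv <- led$filters_pass
  expect_equal(led$q_postfilter[surv],
               benjamini_hochberg(led$p_combined[surv]))
  expect_true(all(is.na(led$q_postfilter[!surv])))
  expect_equal(led$final_status[match(ps$truth[1:2],
               paste(led$cohort, led$element, sep = ":"))],
               c("filtered", "filtered"))
  # surviving planted drivers end significant
  other_drivers <- ps$truth[-(1:2)]
  st <- led$final_status[match(other_drivers,
                               paste(led$cohort, led$element, sep = ":"))]
  expect_true(mean(st == "significant") > 0.7)
  # rerunning the ledger on the same inputs is unchanged (idempotent)
  led2 <- candidate_ledger(ps$pmat, muts)
  expect_equal(led, led2)
})
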