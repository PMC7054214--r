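test_that("binning tiles the genome exactly", {
  g <- genome_def("chr1", 1e6)
  b <- make_bins(g, 1e5)
  expect_equal(nrow(b), 10)
  expect_true(all(b$end - b$start == 1e5))
  expect_equal(b$eligible, rep(1e5, 10))

  g2 <- genome_def("chr1", 250000)
  b2 <- make_bins(g2, 1e5)
  expect_equal(nrow(b2), 3)
  expect_equal(b2$end[3] - b2$start[3], 50000)

  # partition property: every position maps to exactly one bin, and the
  # bin contains it
  b3 <- make_bins(tiny_genome(), 1e5)
  set.seed(1)
  pos <- floor(runif(200) * 1e6)
  idx <- bin_index(b3, rep("chr1", 200), pos)
  expect_false(anyNA(idx))
  expect_true(all(b3$start[idx] <= pos & pos < b3$end[idx]))
  expect_error(make_bins(tiny_genome(), -5), "positive")
})

test_that("mappability scales eligible bases", {
  g <- genome_def("chr1", 4e5)
  tr <- covariate_track("map", rep(0.5, 4))
  b <- make_bins(g, 1e5, mappability = tr)
  expect_equal(b$eligible, rep(5e4, 4))
})

test_that("BEDPE reading canonicalizes and skips unknown chromosomes", {
  f <- write_tmp(c(
    "#chrom1\tstart1\tend1\tchrom2\tstart2\tend2\tname\tscore\ts1\ts2",
    "chr2\t100\t101\tchr1\t5000\t5001\tsampleA\t.\t+\t-",
    "chr1\t200\t201\tchr1\t100\t101\tsampleB\t.\t+\t+",
    "chrUn_xxx\t5\t6\tchr1\t10\t11\tsampleC\t.\t+\t+"), ".bedpe")
  expect_warning(r <- read_bedpe(f, tiny_genome()), "skipped")
  expect_equal(nrow(r), 2)
  expect_equal(attr(r, "n_skipped"), 1)
  # genome order: chr1 before chr2; positions ascending within chrom
  expect_equal(r$chrom1, c("chr1", "chr1"))
  expect_equal(r$pos1, c(5000, 100))
  expect_equal(r$chrom2[1], "chr2")
  expect_equal(r$pos2[2], 200)

  empty <- write_tmp(character(0), ".bedpe")
  expect_equal(nrow(read_bedpe(empty, tiny_genome())), 0)

  bad <- write_tmp("chr1\t100", ".bedpe")
  expect_error(read_bedpe(bad, tiny_genome()), "line 1")
})

test_that("element BED is normalized with conserved total length", {
  f <- write_tmp(c("chr1\t100\t200\te1",
                   "chr1\t150\t300\te1",
                   "chr2\t0\t50\te2\tpromoter"), ".bed")
  e <- read_elements(f)
  expect_equal(sum(e$end[e$id == "e1"] - e$start[e$id == "e1"]), 200)
  expect_equal(unname(attr(e, "total_length")["e1"]), 200)
  expect_equal(e$element_type[e$id == "e2"], "promoter")
  # idempotent
  e2 <- normalize_elements(e)
  expect_equal(as.data.frame(e2), as.data.frame(e))
})

test_that("single BED line gives half-open length", {
  f <- write_tmp("chr1\t100\t200\te1", ".bed")
  e <- read_elements(f)
  expect_equal(unname(attr(e, "total_length")["e1"]), 100)
})

test_that("mutation reading derives variant type and indel length", {
  f <- write_tmp(c("chrom\tpos\tref\talt\tsample",
                   "chr1\t100\tA\tT\ts1",
                   "chr1\t200\tA\tACG\ts1",
                   "chr1\t300\tATT\tA\ts2"), ".tsv")
  m <- read_mutations(f)
  expect_equal(m$var_type, c("SNV", "INS", "DEL"))
  expect_equal(m$indel_length, c(0, 2, 2))
  # explicit 1-based conversion, never silent
  m1 <- read_mutations(f, one_based = TRUE)
  expect_equal(m1$pos, m$pos - 1)
})

test_that("coordinate conversions are mutual inverses", {
  x <- c(0, 5, 999)
  expect_equal(to_zero_based(to_one_based(x)), x)
})

test_that("result tables round-trip through TSV", {
  set.seed(42)
  df <- data.frame(locus = sprintf("L%d", 1:5), p = runif(5),
                   q = runif(5), observed = rpois(5, 4),
                   expected = rexp(5), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_results(df, f)
  back <- read_results(f)
  expect_equal(back$locus, df$locus)
  for (col in c("p", "q", "observed", "expected"))
    expect_equal(back[[col]], df[[col]], tolerance = 1e-12)
})

test_that("covariate tracks average values over bins", {
  g <- genome_def("chr1", 3e5)
  f <- write_tmp(c("chr1\t0\t100000\t1.0",
                   "chr1\t100000\t150000\t2.0",
                   "chr1\t150000\t200000\t4.0"), ".tsv")
  tr <- read_track(f, g, 1e5)
  expect_equal(tr$value, c(1.0, 3.0, NA))
})
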