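## Integration of per-element p-values from multiple point-mutation
## driver-discovery methods: calibration QC of each method against the
## uniform null, Brown's method (moment-matched scaled chi-square
## combination of dependent p-values), FDR control over concatenated
## cohorts with significance tiers, and the numeric post-filters that
## remove artefact- and mutational-process-driven candidates.

#' Read a per-method p-value matrix from long-format TSV
#'
#' Columns: `cohort`, `element`, `method`, `p`. Rows are cohort-element
#' combinations, columns methods; missing entries NA.
#'
#' @param path Path to the TSV file.
#' @return A `pvalue_matrix`: list with matrix `p` (rows named
#'   `cohort:element`), `cohort`, `element`.
#' @export
read_pvalue_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cohort", "element", "method", "p")
  if (!all(need %in% names(df)))
    stop("p-value table needs columns: ", paste(need, collapse = ", "))
  pvalue_matrix(df$cohort, df$element, df$method, df$p)
}

#' Construct a p-value matrix from long vectors
#'
#' @param cohort,element,method,p Parallel vectors (one entry per
#'   cohort-element-method result).
#' @return A `pvalue_matrix` object.
#' @export
pvalue_matrix <- function(cohort, element, method, p) {
  row_key <- paste(cohort, element, sep = ":")
  rows <- unique(row_key)
  methods <- sort(unique(method))
  m <- matrix(NA_real_, length(rows), length(methods),
              dimnames = list(rows, methods))
  m[cbind(match(row_key, rows), match(method, methods))] <- p
  keep <- rowSums(!is.na(m)) >= 1
  m <- m[keep, , drop = FALSE]
  first <- !duplicated(row_key)
  info <- data.frame(key = row_key[first], cohort = cohort[first],
                     element = element[first], stringsAsFactors = FALSE)
  info <- info[info$key %in% rownames(m), ]
  structure(list(p = m, cohort = info$cohort[match(rownames(m), info$key)],
                 element = info$element[match(rownames(m), info$key)]),
            class = "pvalue_matrix")
}

#' Calibration QC of driver-discovery methods
#'
#' Methods whose p-value distributions deviate strongly from the uniform
#' null are dropped before combination. Per method: the inflation factor
#' lambda = median(-2 ln p) / median of a chi-square(2), and the
#' Kolmogorov-Smirnov distance from Uniform(0.1, 1) over the
#' presumed-null bulk (the method's own p-values above 0.1, a
#' null-dominated region since true drivers concentrate in the lower
#' tail). A method is kept
#' when lambda lies within `lambda_bounds` and the KS distance is at most
#' `ks_max`. Methods with more than half their entries missing are
#' assessed on the non-missing entries and flagged `low_coverage`.
#'
#' @param pmat A `pvalue_matrix`.
#' @param lambda_bounds Acceptable inflation range (default `c(0.7, 1.5)`).
#' @param ks_max Maximum KS distance (default 0.1).
#' @param min_rows Minimum non-missing entries to assess a method.
#' @return data.frame per method: `method`, `n`, `lambda`, `ks`, `keep`,
#'   `low_coverage`.
#' @export
calibrate_methods <- function(pmat, lambda_bounds = c(0.7, 1.5),
                              ks_max = 0.1, min_rows = 50) {
  m <- pmat$p
  chisq2_med <- stats::qchisq(0.5, df = 2)
  res <- do.call(rbind, lapply(colnames(m), function(meth) {
    p <- m[, meth]
    ok <- !is.na(p)
    n <- sum(ok)
    if (n < min_rows)
      return(data.frame(method = meth, n = n, lambda = NA, ks = NA,
                        keep = FALSE, low_coverage = TRUE,
                        stringsAsFactors = FALSE))
    lambda <- stats::median(-2 * log(pmax(p[ok], 1e-300))) / chisq2_med
    ## presumed-null bulk: the method's own p above 0.1. True drivers are
    ## rare and concentrate in the lower tail, so this region is
    ## null-dominated, and unlike cross-method conditioning it carries no
    ## selection bias when methods are correlated
    pb <- p[ok & p > 0.1]
    ks <- if (length(pb) >= 10)
      suppressWarnings(stats::ks.test(pb, "punif", min = 0.1,
                                      max = 1)$statistic) else NA_real_
    ## with a small bulk the KS distance is noisy: floor the cut at the
    ## 1%-level KS critical value for the bulk size
    ks_cut <- max(ks_max, 1.63 / sqrt(max(length(pb), 1)))
    keep <- lambda >= lambda_bounds[1] && lambda <= lambda_bounds[2] &&
      (is.na(ks) || ks <= ks_cut)
    data.frame(method = meth, n = n, lambda = lambda, ks = as.numeric(ks),
               keep = keep, low_coverage = mean(ok) < 0.5,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  if (!any(res$keep))
    stop("all methods failed calibration; review lambda_bounds/ks_max")
  res
}

#' Covariance of the -2 ln p transforms across methods
#'
#' Estimated empirically over all rows with pairwise-complete
#' observations, via rank (Spearman) correlation converted to the
#' Gaussian-scale correlation (2 sin(pi r / 6)) and mapped to the
#' covariance of -2 ln p with the Kost-McDermott polynomial
#' (3.263 r + 0.710 r^2 + 0.027 r^3). Rank-based estimation keeps the
#' handful of true-signal rows from inflating the dependence estimate.
#' Negative eigenvalues are clipped to zero (positive semidefinite
#' projection). Perfectly duplicated methods get covariance 4, the null
#' variance of -2 ln p; independent methods get 0 (Fisher).
#'
#' @param pmat A `pvalue_matrix` (possibly subset to calibrated methods).
#' @return Method-by-method covariance matrix of -2 ln p (diagonal 4).
#' @export
estimate_logp_covariance <- function(pmat) {
  rs <- suppressWarnings(
    stats::cor(pmat$p, method = "spearman",
               use = "pairwise.complete.obs"))
  rs[is.na(rs)] <- 0
  r <- 2 * sin(pi * rs / 6)
  cv <- 3.263 * r + 0.710 * r^2 + 0.027 * r^3
  diag(cv) <- 4
  eg <- eigen((cv + t(cv)) / 2, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  eg$vectors %*% diag(vals, nrow = length(vals)) %*% t(eg$vectors)
}

#' Combine one row of p-values with Brown's method
#'
#' Fisher's statistic X = sum(-2 ln p_i) is referred to a scaled
#' chi-square whose first two moments match X under the estimated
#' dependence: E = 2k, V = 4k + 2 sum_{i<j} cov(-2 ln p_i, -2 ln p_j),
#' scale c = V / (2E), degrees of freedom f = 2 E^2 / V; combined
#' p = P(chi^2_f >= X / c). With one method this is the identity; with
#' zero covariance it is exactly Fisher's method.
#'
#' @param p Numeric vector of per-method p-values (NA = method missing).
#' @param covariance Method-by-method covariance of -2 ln p (rows/columns
#'   matching `p`); NULL or all-zero gives Fisher's method.
#' @return Combined p-value.
#' @export
brown_combine <- function(p, covariance = NULL) {
  obs <- which(!is.na(p))
  k <- length(obs)
  if (k == 0) return(NA_real_)
  pv <- p[obs]
  if (any(pv <= 0)) {
    warning("p-value(s) <= 0 clamped to 1e-300")
    pv <- pmax(pv, 1e-300)
  }
  if (k == 1) return(pv)
  X <- sum(-2 * log(pv))
  E <- 2 * k
  V <- 4 * k
  if (!is.null(covariance)) {
    cv <- covariance[obs, obs, drop = FALSE]
    V <- 4 * k + 2 * sum(cv[upper.tri(cv)])
  }
  if (V <= 0) V <- 4 * k
  cc <- V / (2 * E)
  f <- 2 * E^2 / V
  stats::pchisq(X / cc, df = f, lower.tail = FALSE)
}

#' Combine all rows of a p-value matrix
#'
#' @param pmat A `pvalue_matrix`.
#' @param covariance Optional covariance of -2 ln p; by default estimated
#'   with [estimate_logp_covariance()]. Pass a zero matrix for Fisher.
#' @return data.frame: `cohort`, `element`, `k` (methods used),
#'   `p_combined`.
#' @export
combine_matrix <- function(pmat, covariance = NULL) {
  if (is.null(covariance)) covariance <- estimate_logp_covariance(pmat)
  pc <- apply(pmat$p, 1, brown_combine, covariance = covariance)
  data.frame(cohort = pmat$cohort, element = pmat$element,
             k = rowSums(!is.na(pmat$p)), p_combined = as.numeric(pc),
             stringsAsFactors = FALSE)
}

#' FDR over concatenated cohorts with significance tiers
#'
#' BH over the concatenated vector of combined p-values from all
#' tumour-type cohorts. Tiers: `significant` (q < 0.1), `near`
#' (0.1 <= q < 0.25), `ns` otherwise.
#'
#' @param combined data.frame from [combine_matrix()] (or any frame with a
#'   `p_combined` column).
#' @return The input with `q` and `tier` columns appended.
#' @export
concat_fdr <- function(combined) {
  combined$q <- benjamini_hochberg(combined$p_combined)
  combined$tier <- ifelse(combined$q < 0.1, "significant",
                   ifelse(combined$q < 0.25, "near", "ns"))
  combined
}

#' Post-filters for one candidate element
#'
#' Measures, over the mutations falling in the candidate element:
#' mutation and patient counts, mappable fraction, palindromic-DNA
#' fraction, and the fractions attributed (per-mutation maximum-likelihood
#' assignment over the `sig_*` columns) to the APOBEC, AID and UV
#' signatures. A candidate fails when n_mutations < 3, n_patients < 3,
#' mappable fraction <= 0.5, palindrome fraction >= 0.5, or APOBEC
#' fraction >= 0.5; lymphoid cohorts additionally fail at AID fraction
#' >= 0.35 and melanoma at UV fraction >= 0.5. Filters whose annotation is
#' absent are marked not-evaluable (NA pass) and do not fail the
#' candidate, but are flagged.
#'
#' @param muts `mutations` rows falling in the element for the tested
#'   cohort.
#' @param cohort_type One of "lymphoid", "melanoma", or anything else.
#' @return data.frame with one row per filter: `filter`, `value`,
#'   `threshold`, `pass` (NA = not evaluable), `applicable`; overall
#'   verdict in attribute `pass` (TRUE only if every applicable,
#'   evaluable filter passes) and `evaluable`.
#' @export
apply_filters <- function(muts, cohort_type = "other") {
  n_mut <- nrow(muts)
  n_pat <- length(unique(muts$sample))
  frac <- function(col) if (col %in% names(muts) && n_mut > 0)
    mean(muts[[col]], na.rm = TRUE) else NA_real_
  sig_cols <- grep("^sig_", names(muts), value = TRUE)
  sig_frac <- function(sig) {
    col <- paste0("sig_", sig)
    if (!col %in% sig_cols || n_mut == 0) return(NA_real_)
    ml <- apply(muts[, sig_cols, drop = FALSE], 1, function(v)
      if (all(is.na(v))) NA_character_ else sig_cols[which.max(v)])
    mean(ml == col, na.rm = TRUE)
  }
  flags <- data.frame(
    filter = c("n_mutations", "n_patients", "mappable_frac",
               "palindrome_frac", "apobec_frac", "aid_frac", "uv_frac"),
    value = c(n_mut, n_pat, frac("in_mappable"), frac("in_palindrome"),
              sig_frac("apobec"), sig_frac("aid"), sig_frac("uv")),
    threshold = c(3, 3, 0.5, 0.5, 0.5, 0.35, 0.5),
    applicable = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                   cohort_type == "lymphoid", cohort_type == "melanoma"),
    stringsAsFactors = FALSE)
  pass <- c(n_mut >= 3, n_pat >= 3,
            flags$value[3] > 0.5, flags$value[4] < 0.5,
            flags$value[5] < 0.5, flags$value[6] < 0.35,
            flags$value[7] < 0.5)
  flags$pass <- ifelse(flags$applicable, pass, NA)
  evaluable <- !flags$applicable | !is.na(flags$pass)
  overall <- all(flags$pass[flags$applicable & !is.na(flags$pass)])
  attr(flags, "pass") <- overall
  attr(flags, "evaluable") <- all(evaluable)
  flags
}

#' Build the candidate ledger: combine, tier, filter, re-FDR
#'
#' Runs the full integration path: Brown combination of the method
#' p-values, concatenated-cohort FDR with tiers, the numeric post-filters
#' for each candidate, and recomputation of the FDR over the filter
#' survivors. The final status is `significant` only for rows that were
#' significant before filtering, pass every applicable filter, and keep
#' q < 0.1 in the post-filter FDR.
#'
#' @param pmat A `pvalue_matrix`.
#' @param mutations_by_key Named list: for key `cohort:element`, the
#'   `mutations` rows in that element/cohort (used by the filters). Keys
#'   absent from the list are treated as having no mutation-level
#'   annotation (filters not evaluable, flagged).
#' @param cohort_types Named character vector mapping cohort name to
#'   "lymphoid"/"melanoma"/"other" (default "other").
#' @param covariance Optional covariance for [brown_combine()].
#' @return data.frame ledger: cohort, element, k, p_combined, q, tier, the
#'   seven measured filter values, `filters_pass`, `q_postfilter`,
#'   `final_status`.
#' @export
candidate_ledger <- function(pmat, mutations_by_key = list(),
                             cohort_types = character(0),
                             covariance = NULL) {
  led <- concat_fdr(combine_matrix(pmat, covariance))
  key <- paste(led$cohort, led$element, sep = ":")
  ctype <- function(co) {
    t <- cohort_types[co]
    ifelse(is.na(t), "other", t)
  }
  fl <- lapply(seq_len(nrow(led)), function(i) {
    muts <- mutations_by_key[[key[i]]]
    if (is.null(muts))
      muts <- structure(data.frame(sample = character(0)),
                        class = c("mutations", "data.frame"))
    apply_filters(muts, ctype(led$cohort[i]))
  })
  vals <- t(vapply(fl, function(f) f$value, numeric(7)))
  colnames(vals) <- fl[[1]]$filter
  led <- cbind(led, as.data.frame(vals))
  led$filters_pass <- vapply(fl, attr, TRUE, "pass")
  led$filters_evaluable <- vapply(fl, attr, TRUE, "evaluable")
  ## FDR recalculated after post-filtering, over the survivor set
  led$q_postfilter <- NA_real_
  surv <- which(led$filters_pass)
  if (length(surv))
    led$q_postfilter[surv] <- benjamini_hochberg(led$p_combined[surv])
  led$final_status <- ifelse(
    led$tier == "significant" & led$filters_pass &
      !is.na(led$q_postfilter) & led$q_postfilter < 0.1,
    "significant",
    ifelse(led$tier %in% c("significant", "near") & !led$filters_pass,
           "filtered", led$tier))
  led
}
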