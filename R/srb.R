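## Significantly recurrent breakpoint (SRB) detection: per-bin breakpoint
## counts tested against a covariate-aware Gamma-Poisson background with
## mappability exposure as an offset, BH FDR, merging of significant bins
## into loci, rearrangement dispersion scoring and fusion/fragile/SCNA
## classification.

#' Upper-tail probability of a Gamma-Poisson (negative binomial) count
#'
#' Returns P(X >= k) for X distributed Gamma-Poisson with mean `mu` and
#' overdispersion `alpha` (variance mu + alpha * mu^2). `alpha = 0` is the
#' Poisson limit. Vectorized over all arguments.
#'
#' @param k Observed count(s), non-negative integers.
#' @param mu Expected count(s), positive.
#' @param alpha Overdispersion parameter(s), >= 0.
#' @return P(X >= k); 1 wherever `k <= 0`.
#' @export
gp_tail <- function(k, mu, alpha = 0) {
  n <- max(length(k), length(mu), length(alpha))
  k <- rep_len(k, n); mu <- rep_len(mu, n); alpha <- rep_len(alpha, n)
  if (any(k < 0)) stop("observed counts must be non-negative")
  if (any(alpha < 0)) stop("alpha must be >= 0")
  p <- numeric(n)
  pois <- alpha < 1e-12
  p[pois] <- stats::ppois(k[pois] - 1, mu[pois], lower.tail = FALSE)
  if (any(!pois))
    p[!pois] <- stats::pnbinom(k[!pois] - 1, size = 1 / alpha[!pois],
                               mu = mu[!pois], lower.tail = FALSE)
  p[k <= 0] <- 1
  p
}

#' Count breakpoints per bin with per-sample deduplication
#'
#' Both ends of every rearrangement are assigned to their bins; each sample
#' then contributes at most one breakpoint to any one bin, however many of
#' its breakpoints fall there.
#'
#' @param rearrs A `rearrangements` table (see [read_bedpe()]).
#' @param bins Bins from [make_bins()].
#' @param dedup One breakpoint per sample per bin (default TRUE, the
#'   counting rule of the recurrence test); FALSE counts every end (raw
#'   break rates, e.g. as exposure for the juxtaposition background).
#' @return Integer vector of breakpoint counts, one per bin.
#' @export
count_breakpoints <- function(rearrs, bins, dedup = TRUE) {
  counts <- integer(nrow(bins))
  if (!nrow(rearrs)) return(counts)
  b <- c(bin_index(bins, rearrs$chrom1, rearrs$pos1),
         bin_index(bins, rearrs$chrom2, rearrs$pos2))
  keep <- !is.na(b)
  if (dedup) {
    s <- rep(rearrs$sample, 2)
    keep <- !duplicated(paste0(s, "\r", b)) & keep
  }
  tab <- tabulate(b[keep], nbins = nrow(bins))
  as.integer(tab)
}

#' Fit the Gamma-Poisson breakpoint background model
#'
#' Log-linear mean with mappable-base exposure as offset:
#' log mu = b0 + sum_k b_k x_k + log(eligible). The overdispersion alpha
#' (variance mu + alpha mu^2) is estimated by maximum likelihood via
#' [MASS::glm.nb()]; data indistinguishable from Poisson fall back to a
#' Poisson GLM with alpha = 0. Bins whose eligible bases are below
#' `min_eligible_frac` of the bin width are excluded from fitting and
#' testing (exposure too unstable).
#'
#' @param counts Per-bin counts from [count_breakpoints()].
#' @param covariates List of `covariate_track`s aligned to `bins`.
#' @param bins Bins from [make_bins()].
#' @param min_eligible_frac Minimum eligible fraction for a bin to enter
#'   the model (default 0.1).
#' @return Object of class `srb_background`: coefficients, `alpha`,
#'   per-bin fitted means `mu` (NA for excluded bins), logical `included`,
#'   model `deviance`.
#' @export
fit_background <- function(counts, covariates, bins,
                           min_eligible_frac = 0.1) {
  if (!length(covariates)) stop("at least one covariate is required")
  X <- do.call(cbind, lapply(covariates, function(tr) tr$value))
  colnames(X) <- vapply(seq_along(covariates), function(i) {
    nm <- attr(covariates[[i]], "name")
    if (is.null(nm) || !nzchar(nm)) paste0("x", i) else nm
  }, "")
  if (nrow(X) != nrow(bins))
    stop("covariate tracks and bins have different lengths")
  width <- attr(bins, "width")
  included <- bins$eligible >= min_eligible_frac * width &
    rowSums(is.na(X)) == 0
  if (sum(included) < ncol(X) + 2)
    stop("too few eligible bins to fit the background model")
  Xi <- X[included, , drop = FALSE]
  ## collinearity guard: constant columns or |r| > 0.999 between columns
  sds <- apply(Xi, 2, stats::sd)
  if (any(sds == 0))
    stop("collinear covariates: '", colnames(Xi)[sds == 0][1],
         "' is constant (aliased with the intercept)")
  if (ncol(Xi) > 1) {
    r <- stats::cor(Xi)
    r[upper.tri(r, diag = TRUE)] <- 0
    if (any(abs(r) > 0.999)) {
      ij <- which(abs(r) > 0.999, arr.ind = TRUE)[1, ]
      stop("collinear covariates: '", colnames(Xi)[ij[2]], "' and '",
           colnames(Xi)[ij[1]], "' have |r| > 0.999")
    }
  }
  dat <- data.frame(y = counts[included], Xi,
                    off = log(bins$eligible[included]))
  form <- stats::as.formula(paste(
    "y ~", paste(colnames(Xi), collapse = " + "), "+ offset(off)"))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(form, data = dat,
                                  control = stats::glm.control(maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$theta) || fit$theta > 1e7) {
    ## Poisson limit: no measurable overdispersion
    fit <- stats::glm(form, data = dat, family = stats::poisson())
    if (!fit$converged)
      stop("background model did not converge after ", fit$iter,
           " IWLS iterations")
    alpha <- 0
  } else {
    if (!fit$converged)
      stop("background model did not converge after ", fit$iter,
           " IWLS iterations (theta trace: ",
           format(fit$theta, digits = 4), ")")
    alpha <- 1 / fit$theta
  }
  mu <- rep(NA_real_, nrow(bins))
  mu[included] <- as.numeric(stats::fitted(fit))
  structure(list(coefficients = stats::coef(fit), alpha = alpha,
                 mu = mu, included = included,
                 deviance = stats::deviance(fit),
                 exposure_mode = "eligible_bases_offset"),
            class = "srb_background")
}

#' @export
print.srb_background <- function(x, ...) {
  cat("<srb_background> Gamma-Poisson, alpha =",
      format(x$alpha, digits = 4), "\n")
  cat("  coefficients:\n")
  print(x$coefficients)
  cat("  deviance:", format(x$deviance, digits = 6),
      " bins used:", sum(x$included), "\n")
  invisible(x)
}

#' Per-bin SRB p-values
#'
#' p = P(X >= observed) under the fitted Gamma-Poisson background; p = 1
#' where observed = 0; NA for bins excluded from the model.
#'
#' @param model A fitted [fit_background()] model.
#' @param counts Per-bin observed counts.
#' @param bins Bins the model was fitted on.
#' @return Numeric vector of p-values, one per bin.
#' @export
srb_pvalues <- function(model, counts, bins) {
  if (length(counts) != length(model$mu))
    stop("counts and model refer to different binnings")
  if (any(counts < 0)) stop("observed counts must be non-negative")
  p <- rep(NA_real_, length(counts))
  ok <- model$included
  p[ok] <- gp_tail(counts[ok], model$mu[ok], model$alpha)
  p
}

#' Merge significant bins into disjoint SRB loci
#'
#' Adjacent (book-ended, same-chromosome) bins with q below the threshold
#' are merged into maximal runs. Locus statistics: minimum p and q over the
#' merged bins, summed observed, summed expected.
#'
#' @param bins Bins from [make_bins()].
#' @param observed,expected,p,q Per-bin vectors (NA allowed where untested).
#' @param q_threshold Significance threshold on q (default 0.1).
#' @return data.frame with one row per locus: `locus`, `chrom`, `start`,
#'   `end`, `n_bins`, `observed`, `expected`, `p`, `q` and a list column
#'   `bin_idx` of member bin indices.
#' @export
merge_loci <- function(bins, observed, expected, p, q, q_threshold = 0.1) {
  sig <- which(!is.na(q) & q < q_threshold)
  if (!length(sig))
    return(data.frame(locus = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_bins = integer(0), observed = numeric(0),
                      expected = numeric(0), p = numeric(0), q = numeric(0)))
  adjacent <- c(FALSE, diff(sig) == 1 &
                  bins$chrom[sig[-1]] == bins$chrom[sig[-length(sig)]] &
                  bins$start[sig[-1]] == bins$end[sig[-length(sig)]])
  grp <- cumsum(!adjacent)
  runs <- split(sig, grp)
  out <- do.call(rbind, lapply(seq_along(runs), function(i) {
    idx <- runs[[i]]
    data.frame(locus = sprintf("srb_%03d", i), chrom = bins$chrom[idx[1]],
               start = bins$start[idx[1]], end = bins$end[idx[length(idx)]],
               n_bins = length(idx), observed = sum(observed[idx]),
               expected = sum(expected[idx]), p = min(p[idx]),
               q = min(q[idx]), stringsAsFactors = FALSE)
  }))
  out$bin_idx <- unname(runs)
  out
}

#' Rearrangement dispersion score of an SRB locus
#'
#' For every rearrangement with a breakpoint inside the locus, the partner
#' breakpoint is assigned to its genome bin; the score is the Shannon
#' entropy of the partner-bin frequency distribution divided by
#' log(number of partner breakpoints). 0 means all partners share one bin
#' (fusion-like clustering); values near 1 mean all partners are distinct
#' (fragile/SCNA-like scatter). Undefined (NA) with fewer than 2 partners.
#'
#' @param locus_bins Integer indices of the locus's member bins.
#' @param rearrs A `rearrangements` table.
#' @param bins Bins from [make_bins()].
#' @return Score in `[0, 1]`, or NA.
#' @export
dispersion_score <- function(locus_bins, rearrs, bins) {
  if (!nrow(rearrs)) return(NA_real_)
  b1 <- bin_index(bins, rearrs$chrom1, rearrs$pos1)
  b2 <- bin_index(bins, rearrs$chrom2, rearrs$pos2)
  partners <- c(b2[b1 %in% locus_bins], b1[b2 %in% locus_bins])
  partners <- partners[!is.na(partners)]
  n <- length(partners)
  if (n < 2) return(NA_real_)
  f <- tabulate(factor(partners)) / n
  H <- -sum(f * log(f))
  H / log(n)
}

#' Classify an SRB locus
#'
#' Decision tree: fusion-like if the dispersion score is at or below
#' `d_thresh`; otherwise fragile-like if the mean replication-timing score
#' of the locus (1 = latest replication) exceeds 0.5; otherwise
#' amplification / deletion / copy-neutral by the sign of the mean
#' copy-number change across the locus breakpoints (|change| < 0.1 copies
#' is copy-neutral).
#'
#' @param dispersion Dispersion score of the locus (NA allowed).
#' @param mean_rep_timing Mean replication-timing score in `[0, 1]`, or NA.
#' @param cn_change Mean copy-number change across locus breakpoints.
#' @param d_thresh Fusion threshold on the dispersion score (default 0.2).
#' @return Character class: one of `fusion-like`, `fragile-like`,
#'   `amplification`, `deletion`, `copy-neutral`, or
#'   `unclassified-fragility` when the timing score needed for the split is
#'   missing.
#' @export
classify_srb <- function(dispersion, mean_rep_timing, cn_change = 0,
                         d_thresh = 0.2) {
  if (!is.na(dispersion) && dispersion <= d_thresh) return("fusion-like")
  if (is.na(mean_rep_timing)) return("unclassified-fragility")
  if (mean_rep_timing > 0.5) return("fragile-like")
  if (is.na(cn_change) || abs(cn_change) < 0.1) return("copy-neutral")
  if (cn_change > 0) "amplification" else "deletion"
}

#' Full SRB scan: counts, background, testing, merging, classification
#'
#' @param rearrs A `rearrangements` table.
#' @param bins Bins from [make_bins()].
#' @param covariates List of `covariate_track`s used in the background.
#' @param q_threshold FDR threshold for locus calling (default 0.1).
#' @param rep_timing Optional replication-timing `covariate_track` scaled to
#'   `[0, 1]` (1 = latest) used for fragile-site classification.
#' @param cn_change Optional per-bin copy-number change track.
#' @param d_thresh Fusion threshold on the dispersion score.
#' @param min_eligible_frac Passed to [fit_background()].
#' @return List with per-bin table `bins` (observed, expected, p, q), the
#'   fitted `model`, and the locus table `loci` (with dispersion,
#'   mean_rep_timing and class columns).
#' @export
srb_scan <- function(rearrs, bins, covariates, q_threshold = 0.1,
                     rep_timing = NULL, cn_change = NULL, d_thresh = 0.2,
                     min_eligible_frac = 0.1) {
  counts <- count_breakpoints(rearrs, bins)
  model <- fit_background(counts, covariates, bins,
                          min_eligible_frac = min_eligible_frac)
  p <- srb_pvalues(model, counts, bins)
  q <- rep(NA_real_, length(p))
  q[model$included] <- benjamini_hochberg(p[model$included])
  loci <- merge_loci(bins, counts, model$mu, p, q, q_threshold)
  if (nrow(loci)) {
    loci$dispersion <- vapply(loci$bin_idx, dispersion_score, 0,
                              rearrs = rearrs, bins = bins)
    loci$mean_rep_timing <- vapply(loci$bin_idx, function(idx)
      if (is.null(rep_timing)) NA_real_ else
        mean(rep_timing$value[idx], na.rm = TRUE), 0)
    loci$cn_change <- vapply(loci$bin_idx, function(idx)
      if (is.null(cn_change)) NA_real_ else
        mean(cn_change$value[idx], na.rm = TRUE), 0)
    loci$class <- mapply(classify_srb, loci$dispersion,
                         loci$mean_rep_timing, loci$cn_change,
                         MoreArgs = list(d_thresh = d_thresh))
  }
  bin_table <- data.frame(chrom = bins$chrom, start = bins$start,
                          end = bins$end, observed = counts,
                          expected = model$mu, p = p, q = q)
  list(bins = bin_table, model = model, loci = loci)
}
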