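## Negative-binomial-regression burden testing over arbitrary element
## sets (including a 2-kb genome-wide window scan) and estimation of the
## excess (driver) mutation count with exact confidence intervals. The
## background model is fitted on putative passenger elements with a
## log-length offset and covariates such as local mutation rate,
## expression and copy number; candidate sets are then compared to their
## predicted passenger expectation.

#' Fit the negative-binomial burden background on passenger elements
#'
#' Log-link NB regression of per-element mutation counts on covariates
#' with log(element length), optionally times cohort size, as offset;
#' dispersion theta by maximum likelihood ([MASS::glm.nb()]). Elements of
#' length zero are excluded with a warning. Fit SNVs and indels
#' separately.
#'
#' @param counts Non-negative integer mutation counts per passenger
#'   element.
#' @param covariates data.frame or matrix of per-element covariates (NULL
#'   for an intercept-only model, which reduces to the method-of-moments
#'   rate).
#' @param length_bp Element lengths (offset = log length).
#' @param min_elements Minimum number of passenger elements (default 100).
#' @return Object of class `nbr_model`: `coefficients`, `theta`, `alpha`
#'   (= 1/theta), `deviance` and the covariate names.
#' @export
fit_nbr <- function(counts, covariates = NULL, length_bp,
                    min_elements = 100) {
  keep <- length_bp > 0
  if (any(!keep)) {
    warning(sum(!keep), " element(s) of length 0 excluded from NBR fit")
    counts <- counts[keep]; length_bp <- length_bp[keep]
    if (!is.null(covariates))
      covariates <- covariates[keep, , drop = FALSE]
  }
  if (length(counts) < min_elements)
    stop("NBR needs at least ", min_elements, " passenger elements")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  dat <- data.frame(y = counts, off = log(length_bp))
  terms <- "1"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    sds <- vapply(covariates, stats::sd, 0)
    covariates <- covariates[, sds > 0, drop = FALSE]
    if (ncol(covariates)) {
      dat <- cbind(dat, covariates)
      terms <- paste(colnames(covariates), collapse = " + ")
    }
  }
  form <- stats::as.formula(paste("y ~", terms, "+ offset(off)"))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(form, data = dat,
                                  control = stats::glm.control(maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$theta) || fit$theta > 1e7) {
    fit <- stats::glm(form, data = dat, family = stats::poisson())
    if (!fit$converged)
      stop("NBR did not converge after ", fit$iter, " IWLS iterations")
    theta <- Inf
  } else {
    if (!fit$converged)
      stop("NBR did not converge after ", fit$iter, " IWLS iterations")
    theta <- fit$theta
  }
  structure(list(coefficients = stats::coef(fit), theta = theta,
                 alpha = if (is.finite(theta)) 1 / theta else 0,
                 deviance = stats::deviance(fit),
                 covariate_names = setdiff(names(dat), c("y", "off"))),
            class = "nbr_model")
}

#' @export
print.nbr_model <- function(x, ...) {
  cat("<nbr_model> theta =", format(x$theta, digits = 4),
      " (alpha =", format(x$alpha, digits = 4), ")\n")
  print(x$coefficients)
  invisible(x)
}

#' Expected mutation counts under a fitted NBR model
#'
#' @param model An `nbr_model`.
#' @param covariates Per-element covariates (NULL for intercept-only).
#' @param length_bp Element lengths.
#' @return Expected counts mu per element.
#' @export
predict_nbr <- function(model, covariates = NULL, length_bp) {
  eta <- model$coefficients[["(Intercept)"]] + log(length_bp)
  if (length(model$covariate_names)) {
    covariates <- as.data.frame(covariates)
    for (nm in model$covariate_names)
      eta <- eta + model$coefficients[[nm]] * covariates[[nm]]
  }
  unname(exp(eta))
}

#' Negative-binomial burden test
#'
#' Upper-tail p = P(X >= observed) under the fitted background
#' expectation and dispersion; p = 1 at observed = 0.
#'
#' @param observed Observed counts.
#' @param expected Expected counts from [predict_nbr()].
#' @param model An `nbr_model` (supplies the dispersion), or NULL with
#'   `alpha` given directly.
#' @param alpha Overdispersion; overrides `model`.
#' @return p-values.
#' @export
burden_test <- function(observed, expected, model = NULL, alpha = NULL) {
  if (is.null(alpha)) {
    if (is.null(model)) stop("need a model or alpha")
    alpha <- model$alpha
  }
  gp_tail(observed, expected, alpha)
}

#' Genome-wide window scan for element-independent recurrence
#'
#' Tiles the genome into fixed-width windows (default 2 kb), counts
#' mutations per window, fits the NBR background over all windows (the
#' overwhelming majority being passengers) and tests each window's
#' burden, with BH correction within the scanned set.
#'
#' @param mutations A `mutations` table.
#' @param genome A [genome_def()].
#' @param width Window width in bp (default 2000).
#' @param covariates Optional per-window covariate data.frame.
#' @return List: `windows` data.frame (chrom, start, end, observed,
#'   expected, p, q) and the fitted `model`.
#' @export
window_scan <- function(mutations, genome, width = 2000,
                        covariates = NULL) {
  bins <- make_bins(genome, width)
  idx <- bin_index(bins, mutations$chrom, mutations$pos)
  counts <- tabulate(idx[!is.na(idx)], nbins = nrow(bins))
  model <- fit_nbr(counts, covariates, bins$end - bins$start,
                   min_elements = min(100, nrow(bins)))
  expected <- predict_nbr(model, covariates, bins$end - bins$start)
  p <- burden_test(counts, expected, model)
  data_out <- data.frame(chrom = bins$chrom, start = bins$start,
                         end = bins$end, observed = counts,
                         expected = expected, p = p,
                         q = benjamini_hochberg(p))
  list(windows = data_out, model = model)
}

#' Excess (driver) mutations in an element set
#'
#' excess = observed - sum(expected), with a 95% confidence interval from
#' the exact Poisson interval on the observed count (expected treated as
#' fixed), so the lower bound can never fall below -expected.
#'
#' @param observed Total observed mutation count over the set.
#' @param expected Per-element expected counts (summed internally) or a
#'   single total.
#' @param conf_level Confidence level (default 0.95).
#' @return data.frame of class `excess_report`: observed, expected,
#'   excess, ci_lower, ci_upper.
#' @export
excess_mutations <- function(observed, expected, conf_level = 0.95) {
  stopifnot(observed >= 0)
  etot <- sum(expected)
  ci <- stats::poisson.test(round(observed),
                            conf.level = conf_level)$conf.int
  structure(data.frame(observed = observed, expected = etot,
                       excess = observed - etot,
                       ci_lower = ci[1] - etot, ci_upper = ci[2] - etot),
            class = c("excess_report", "data.frame"))
}
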