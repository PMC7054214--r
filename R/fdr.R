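#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: q(i) is the minimum over ranks
#' j >= rank(i) of m * p(j) / j, capped at 1. Ties keep their original
#' order; the adjustment is monotone in rank. NaN input is an error rather
#' than being propagated silently.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjamini_hochberg <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p))) stop("p-values must not be NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
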