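## Discovery-power calculations: the minimal driver frequency detectable
## by an element burden test at >= 90% power given cohort size, background
## rate, element length and detection sensitivity; and the analogous
## calculation for recurrent juxtapositions on the two-dimensional tile
## map.

## smallest k with P(Binom(n, p) >= k) <= alpha
critical_count <- function(n, p, alpha) {
  k <- stats::qbinom(alpha, n, p, lower.tail = FALSE) + 1
  while (k > 1 && binom_tail(k - 1, n, p) <= alpha) k <- k - 1
  while (binom_tail(k, n, p) > alpha) k <- k + 1
  k
}

#' Minimal driver frequency detectable with >= 90% power
#'
#' The burden test on one element rejects when the mutated-patient count
#' reaches the critical value k*, the smallest count whose background
#' binomial tail is below the per-test level alpha_global / n_tests. A
#' driver present in a fraction f of patients, detected with sensitivity
#' s, mutates a patient with probability q0 + f s (1 - q0) (union of
#' independent background and driver events), where
#' q0 = 1 - (1 - bg_rate)^L is the per-patient background probability for
#' an element of length L. The minimal frequency f* is the smallest f
#' whose power P(Binom(N, q0 + f s (1 - q0)) >= k*) reaches `power`,
#' found by bisection to 1e-5.
#'
#' @param n_patients Cohort size N.
#' @param bg_rate Background mutation rate per base per patient.
#' @param length_bp Element length L in bp.
#' @param sensitivity Detection sensitivity s in (0, 1].
#' @param alpha_global Global false-positive rate (default 0.1).
#' @param n_tests Number of elements tested (per-test level =
#'   alpha_global / n_tests).
#' @param power Target power (default 0.9).
#' @return f* in (0, 1], or NA ("not powered") when even f = 1 fails.
#' @export
min_detectable_frequency <- function(n_patients, bg_rate, length_bp,
                                     sensitivity, alpha_global = 0.1,
                                     n_tests = 1, power = 0.9) {
  stopifnot(n_patients > 0, bg_rate > 0, length_bp > 0,
            sensitivity > 0, sensitivity <= 1, n_tests >= 1)
  alpha <- alpha_global / n_tests
  q0 <- 1 - (1 - bg_rate)^length_bp
  kstar <- critical_count(n_patients, q0, alpha)
  pw <- function(f) binom_tail(kstar, n_patients,
                               q0 + f * sensitivity * (1 - q0))
  if (pw(1) < power) return(NA_real_)
  lo <- 0; hi <- 1
  while (hi - lo > 1e-5) {
    mid <- (lo + hi) / 2
    if (pw(mid) >= power) hi <- mid else lo <- mid
  }
  hi
}

#' Power to detect a recurrent juxtaposition
#'
#' Per-tile background probability p0 = median rearrangements per sample
#' spread uniformly over the tile map (or a supplied per-tile p0); the
#' driver tile's per-sample event probability is p0 + recurrence_rate. The
#' critical count k* is set at the tile-level alpha
#' alpha_global / tile_count.
#'
#' @param n_samples Cohort size.
#' @param median_rearr_per_sample Median rearrangement count per sample.
#' @param recurrence_rate Driver juxtaposition frequency above background
#'   (per sample; > 0).
#' @param tile_count Number of tiles in the fusion map.
#' @param alpha_global Global false-positive rate (default 0.1).
#' @param p0 Optional per-tile background probability overriding the
#'   uniform spread.
#' @return Detection power in `[0, 1]` (vector if `p0` is a vector).
#' @export
srj_power <- function(n_samples, median_rearr_per_sample, recurrence_rate,
                      tile_count, alpha_global = 0.1, p0 = NULL) {
  if (any(recurrence_rate <= 0)) stop("recurrence_rate must be positive")
  if (is.null(p0)) p0 <- median_rearr_per_sample / tile_count
  alpha <- alpha_global / tile_count
  vapply(p0, function(p0i) {
    kstar <- critical_count(n_samples, p0i, alpha)
    binom_tail(kstar, n_samples, min(1, p0i + recurrence_rate))
  }, 0)
}

#' Samples required to reach target SRJ power over the tile map
#'
#' Smallest cohort size N such that at least `tile_coverage` of the tiles
#' reach `power` for a juxtaposition recurring at `recurrence_rate`.
#'
#' @inheritParams srj_power
#' @param power Target power (default 0.9).
#' @param tile_coverage Fraction of tiles that must reach the target
#'   (default 0.9; only binding with a non-uniform `p0` map).
#' @return Integer number of samples.
#' @export
samples_required <- function(median_rearr_per_sample, recurrence_rate,
                             tile_count, power = 0.9, tile_coverage = 0.9,
                             alpha_global = 0.1, p0 = NULL) {
  ok <- function(n) {
    pw <- srj_power(n, median_rearr_per_sample, recurrence_rate,
                    tile_count, alpha_global, p0)
    mean(pw >= power) >= tile_coverage
  }
  hi <- 2
  while (!ok(hi)) { hi <- hi * 2; if (hi > 1e7) return(NA_integer_) }
  lo <- hi %/% 2
  while (hi - lo > 1) { mid <- (lo + hi) %/% 2; if (ok(mid)) hi <- mid else lo <- mid }
  as.integer(hi)
}

#' Summarize a per-base detection-sensitivity track over elements
#'
#' @param sens A numeric vector of per-base sensitivities in `[0, 1]` for
#'   one element, or a named list of such vectors (one per element).
#' @return data.frame: `id`, `mean_sensitivity`, `frac_above_0.9`,
#'   `frac_below_0.1`.
#' @export
detection_sensitivity_summary <- function(sens) {
  if (!is.list(sens)) sens <- list(element = sens)
  if (any(!lengths(sens))) stop("empty element in sensitivity summary")
  bad <- vapply(sens, function(s) any(s < 0 | s > 1), TRUE)
  if (any(bad)) stop("sensitivities must lie in [0, 1]")
  data.frame(
    id = if (is.null(names(sens))) as.character(seq_along(sens))
         else names(sens),
    mean_sensitivity = vapply(sens, mean, 0),
    frac_above_0.9 = vapply(sens, function(s) mean(s > 0.9), 0),
    frac_below_0.1 = vapply(sens, function(s) mean(s < 0.1), 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Minimal-frequency power grid
#'
#' Evaluates [min_detectable_frequency()] over the cross of the supplied
#' axes. f* is non-increasing in cohort size and sensitivity and
#' non-decreasing in the background rate.
#'
#' @param n_patients,bg_rate,length_bp,sensitivity Axis values.
#' @param ... Passed to [min_detectable_frequency()].
#' @return data.frame with one row per grid cell and column `f_star`.
#' @export
power_grid <- function(n_patients, bg_rate, length_bp, sensitivity, ...) {
  grid <- expand.grid(n_patients = n_patients, bg_rate = bg_rate,
                      length_bp = length_bp, sensitivity = sensitivity)
  grid$f_star <- mapply(min_detectable_frequency, grid$n_patients,
                        grid$bg_rate, grid$length_bp, grid$sensitivity,
                        MoreArgs = list(...))
  grid
}
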