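## Significantly recurrent juxtaposition (SRJ) detection: pairs of genome
## bins ("tiles" of the two-dimensional fusion map) joined by more
## rearrangements than expected given each locus's break rate and the
## distance between them. Background: two-component mixture
##   p0(i,j) prop.to  w * b_i * b_j  +  (1 - w) * (b_i + b_j) * g(d_ij)
## (two independent breaks joined, versus one break invading a nearby
## locus), with g an empirical intra-chromosomal distance kernel and the
## mixture weight w fitted by multinomial maximum likelihood on a grid.

#' Upper-tail probability of a binomial count
#'
#' P(X >= k) for X ~ Binomial(n, p). Vectorized.
#'
#' @param k Observed count(s).
#' @param n Number of trials.
#' @param p Success probability in (0, 1).
#' @return P(X >= k); 1 wherever `k <= 0`.
#' @export
binom_tail <- function(k, n, p) {
  if (any(p <= 0)) stop("p0 must be positive")
  out <- stats::pbinom(k - 1, n, p, lower.tail = FALSE)
  out[k <= 0] <- 1
  out
}

## map both ends of each rearrangement to canonical tile (i <= j);
## optionally dropping short intra-chromosomal events
tile_of <- function(rearrs, bins, min_event_size = 0) {
  b1 <- bin_index(bins, rearrs$chrom1, rearrs$pos1)
  b2 <- bin_index(bins, rearrs$chrom2, rearrs$pos2)
  keep <- !is.na(b1) & !is.na(b2)
  if (min_event_size > 0)
    keep <- keep & !(rearrs$chrom1 == rearrs$chrom2 &
                       abs(rearrs$pos2 - rearrs$pos1) < min_event_size)
  i <- pmin(b1, b2)[keep]; j <- pmax(b1, b2)[keep]
  data.frame(i = i, j = j, sample = rearrs$sample[keep])
}

#' Count juxtaposition events per tile with per-sample deduplication
#'
#' A tile is the unordered pair of the bins holding a rearrangement's two
#' breakpoints (the diagonal tile when both ends share a bin). Each sample
#' contributes at most one event to any tile.
#'
#' @param rearrs A `rearrangements` table.
#' @param bins Bins from [make_bins()].
#' @param min_event_size Intra-chromosomal events shorter than this (bp)
#'   are dropped as likely artefacts (default 1000).
#' @return data.frame with columns `i`, `j` (bin indices, i <= j) and
#'   `observed` for every tile with at least one event; the total
#'   deduplicated event count is in attribute `n_events`.
#' @export
count_tile_events <- function(rearrs, bins, min_event_size = 1000) {
  tl <- tile_of(rearrs, bins, min_event_size)
  if (!nrow(tl)) {
    out <- data.frame(i = integer(0), j = integer(0), observed = integer(0))
    attr(out, "n_events") <- 0L
    return(out)
  }
  dedup <- !duplicated(paste0(tl$sample, "\r", tl$i, "\r", tl$j))
  tl <- tl[dedup, ]
  key <- paste0(tl$i, "\r", tl$j)
  tab <- table(key)
  ij <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  out <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                    observed = as.integer(tab))
  out <- out[order(out$i, out$j), ]
  rownames(out) <- NULL
  attr(out, "n_events") <- sum(out$observed)
  out
}

#' Fit the juxtaposition background (per-tile null probabilities)
#'
#' Combines per-bin break rates with an empirical distance kernel into the
#' two-component mixture described above; both components are normalized
#' over all tiles, so the returned p0 matrix sums to 1 over the unordered
#' tile universe. The mixture weight w is chosen on a grid (0, 0.05, ..., 1)
#' by maximizing the multinomial likelihood of the observed tile
#' assignments.
#'
#' @param rearrs A `rearrangements` table (used to estimate the distance
#'   kernel and fit w).
#' @param break_rates Per-bin expected break rates, e.g. `mu` from
#'   [fit_background()]; NA or zero marks bins with no exposure.
#' @param bins Bins from [make_bins()].
#' @param n_dist_bins Number of log-spaced distance bins for the kernel.
#' @param min_event_size Passed to the event/tile assignment.
#' @param w_grid Candidate mixture weights.
#' @return Object of class `srj_background`: symmetric matrix `p0` (entry
#'   i, j = null probability of the unordered tile), fitted `w`, the
#'   distance-kernel table, and the logical vector of bins with exposure.
#' @export
fit_juxtaposition_background <- function(rearrs, break_rates, bins,
                                         n_dist_bins = 16,
                                         min_event_size = 1000,
                                         w_grid = seq(0, 1, by = 0.05)) {
  nb <- nrow(bins)
  b <- break_rates
  b[is.na(b)] <- 0
  if (all(b <= 0)) stop("all-zero break rates: background unestimable")
  tl <- tile_of(rearrs, bins, min_event_size)
  if (!nrow(tl)) stop("no usable rearrangements: distance kernel unestimable")

  mid <- (bins$start + bins$end) / 2
  chrom_id <- match(bins$chrom, unique(bins$chrom))
  intra <- outer(chrom_id, chrom_id, "==")
  D <- abs(outer(mid, mid, "-"))
  D[!intra] <- NA

  ## empirical distance kernel on log-spaced bins; +1 smoothing; each
  ## distance class weighted by the number of tiles it contains, so g is a
  ## per-tile rate; inter-chromosomal tiles carry the constant tail mass
  width <- attr(bins, "width")
  d_evt <- ifelse(bins$chrom[tl$i] == bins$chrom[tl$j],
                  abs(mid[tl$j] - mid[tl$i]), NA)
  dmax <- max(D, na.rm = TRUE)
  ## classes: diagonal (distance 0), then lattice-resolved classes
  ## (bin-midpoint distances are multiples of the bin width, and a steep
  ## kernel pooled over a log-spaced class would misstate every tile in
  ## it) for as long as each class keeps decent event support, then
  ## log-spaced tail
  lat <- round(d_evt[!is.na(d_evt)] / width)
  lat_n <- tabulate(lat[lat >= 1], nbins = floor(dmax / width) + 1)
  dense <- which(lat_n >= 30)
  H <- if (length(dense)) min(max(3, max(dense)), 100) else 3
  head_end <- min((H + 0.5) * width, dmax)
  breaks <- unique(c(0, seq(width / 2, head_end, by = width),
                     exp(seq(log(head_end), log(dmax + 1),
                             length.out = max(n_dist_bins - 2, 2)))))
  breaks <- sort(breaks)
  breaks[length(breaks)] <- dmax + 1
  upper <- upper.tri(D, diag = TRUE)
  dcls_tile <- matrix(NA_integer_, nb, nb)
  dcls_tile[intra] <- findInterval(D[intra], breaks,
                                   rightmost.closed = TRUE)
  tiles_per_class <- tabulate(dcls_tile[upper][!is.na(dcls_tile[upper])],
                              nbins = length(breaks))
  n_inter_tiles <- sum(upper & !intra)
  evt_class <- findInterval(d_evt, breaks, rightmost.closed = TRUE)
  evt_per_class <- tabulate(evt_class[!is.na(evt_class)],
                            nbins = length(breaks))
  n_inter_evt <- sum(is.na(d_evt))
  ## break-then-invasion is an intra-chromosomal process: inter tiles get
  ## only a vestigial constant tail mass (0.1% of the farthest distance
  ## class, keeping p0 positive everywhere). Inter-chromosomal events are
  ## thereby carried by the two-break component, which is what makes the
  ## mixture weight identifiable; an empirical inter rate here would let
  ## the kernel absorb the whole mixture and drive w to 0.
  exposure <- b > 0
  mask <- outer(exposure, exposure, "&")
  norm_ut <- function(M) { s <- sum(M[upper]); if (s > 0) M / s else M }
  C1 <- outer(b, b)                 # two breaks, joined
  C1[!mask] <- 0
  C1 <- norm_ut(C1)
  bsum <- outer(b, b, "+")
  idx <- cbind(tl$i, tl$j)

  make_C2 <- function(g_class, g_inter) {
    G <- matrix(g_inter, nb, nb)
    G[intra] <- g_class[dcls_tile[intra]]
    C2 <- bsum * G                  # one break, invasion by distance
    C2[!mask] <- 0
    norm_ut(C2)
  }
  ## kernel decreases with distance by assumption: smooth the raw class
  ## rates with non-increasing isotonic regression (tile-count weighted)
  ## beyond the zero-distance class
  smooth_g <- function(g_class) {
    pop <- which(tiles_per_class > 0)
    if (length(pop) > 2) {
      beyond <- pop[-1]
      g_class[beyond] <- pava_decreasing(g_class[beyond],
                                         tiles_per_class[beyond])
    }
    g_class
  }
  vestigial <- function(g_class) {
    tail_cls <- which(tiles_per_class > 0)
    if (length(tail_cls)) 1e-3 * g_class[max(tail_cls)] else 0
  }
  ## EM for (kernel, w): each event's distance feeds the kernel weighted
  ## by its responsibility under the invasion component. A kernel pooled
  ## over all events would absorb the two-break component's flat intra
  ## floor, over-allocating mass to distant intra tiles and starving
  ## inter tiles.
  g_class <- smooth_g(ifelse(tiles_per_class > 0,
                             (evt_per_class + 1) / tiles_per_class, 0))
  w <- 0.5
  for (iter in 1:50) {
    C2 <- make_C2(g_class, vestigial(g_class))
    p1 <- w * C1[idx]; p2 <- (1 - w) * C2[idx]
    r <- p1 / (p1 + p2)             # responsibility of the two-break part
    r[is.na(r)] <- 0.5
    w_new <- min(max(mean(r), 1e-6), 1 - 1e-6)
    wt_inv <- 1 - r
    ecls <- vapply(seq_along(breaks), function(k)
      sum(wt_inv[!is.na(evt_class) & evt_class == k]), 0)
    g_new <- smooth_g(ifelse(tiles_per_class > 0,
                             (ecls + 1) / tiles_per_class, 0))
    done <- abs(w_new - w) < 1e-4
    w <- w_new; g_class <- g_new
    if (done) break
  }
  ## final mixture weight: profile likelihood on the grid, refined near
  ## the EM value
  C2 <- make_C2(g_class, vestigial(g_class))
  ## refinement points stay inside the span of the user's grid, so a
  ## restricted w_grid acts as a constraint
  refine <- pmin(max(w_grid), pmax(min(w_grid),
                                   seq(max(0, w - 0.06),
                                       min(1, w + 0.06), by = 0.005)))
  grid <- sort(unique(c(w_grid, refine)))
  ll <- vapply(grid, function(wg) {
    p <- wg * C1[idx] + (1 - wg) * C2[idx]
    if (any(p <= 0)) -Inf else sum(log(p))
  }, 0)
  w <- grid[which.max(ll)]
  p0 <- w * C1 + (1 - w) * C2
  structure(list(p0 = p0, w = w, w_loglik = stats::setNames(ll, grid),
                 kernel = data.frame(lower = breaks,
                                     g = g_class, tiles = tiles_per_class),
                 g_inter = vestigial(g_class), exposure = exposure),
            class = "srj_background")
}

#' @export
print.srj_background <- function(x, ...) {
  cat("<srj_background> mixture weight w =", x$w, "\n")
  cat("  bins with exposure:", sum(x$exposure), "of", length(x$exposure), "\n")
  invisible(x)
}

#' Binomial SRJ test for one or more tiles
#'
#' p = P(Binomial(N_total, p0) >= observed).
#'
#' @param observed Deduplicated event count(s) in the tile(s).
#' @param n_total Total deduplicated events genome-wide.
#' @param p0 Per-tile null probabilities (positive).
#' @return p-value(s); 1 where observed = 0.
#' @export
srj_test <- function(observed, n_total, p0) {
  if (any(observed < 0) || any(observed > n_total))
    stop("observed must lie in [0, n_total]")
  binom_tail(observed, n_total, p0)
}

#' Observed/expected effect size
#'
#' @param observed Observed count.
#' @param expected Expected count (> 0).
#' @return observed / expected.
#' @export
effect_size <- function(observed, expected) {
  if (any(expected <= 0)) stop("expected must be positive")
  observed / expected
}

#' Robustness factor of a significant SRJ tile
#'
#' The largest factor r by which the tile's background probability could be
#' multiplied with the tile remaining significant:
#' r = sup { m >= 1 : P(Binomial(N, min(1, m p0)) >= observed) <= alpha }.
#' The tail probability is monotone increasing in m, so the supremum is
#' found by doubling and bisection (relative tolerance 1e-3).
#'
#' @param observed Observed count (tile must be significant at `alpha_tile`).
#' @param n_total Total events.
#' @param p0 Tile null probability.
#' @param alpha_tile Raw-p significance threshold of the current run (the
#'   largest raw p among tiles passing the FDR cut).
#' @return r >= 1, or NA if the tile is not significant at `alpha_tile`.
#' @export
robustness_factor <- function(observed, n_total, p0, alpha_tile) {
  pm <- function(m) binom_tail(observed, n_total, min(1, m * p0))
  if (pm(1) > alpha_tile) return(NA_real_)
  lo <- 1; hi <- 2
  while (pm(hi) <= alpha_tile) {
    lo <- hi; hi <- hi * 2
    if (hi * p0 >= 1 && pm(hi) > alpha_tile) break
    if (hi > 1e12) return(Inf)
  }
  while ((hi - lo) / lo > 1e-3) {
    mid <- (lo + hi) / 2
    if (pm(mid) <= alpha_tile) lo <- mid else hi <- mid
  }
  lo
}

#' Full SRJ scan
#'
#' Counts deduplicated events per tile, fits the mixture background, tests
#' every tile with at least one event, and controls the FDR over the full
#' tile universe (all tiles with nonzero exposure; zero-event tiles enter
#' the correction with p = 1). Effect sizes and robustness factors are
#' reported for significant tiles.
#'
#' @param rearrs A `rearrangements` table.
#' @param bins Bins from [make_bins()].
#' @param break_rates Per-bin break rates (see
#'   [fit_juxtaposition_background()]); defaults to the raw
#'   (non-deduplicated) breakpoint end counts when NULL.
#' @param q_threshold FDR threshold (default 0.1).
#' @param min_event_size Minimum intra-chromosomal event size in bp.
#' @param ... Passed to [fit_juxtaposition_background()].
#' @return List with `tiles` (one row per tested tile: coordinates of both
#'   bins, observed, expected, p, q, effect_size, robustness_factor,
#'   intra), the fitted `background`, total `n_events`, the universe size
#'   `m`, and `alpha_tile`.
#' @export
srj_scan <- function(rearrs, bins, break_rates = NULL, q_threshold = 0.1,
                     min_event_size = 1000, ...) {
  if (is.null(break_rates))
    break_rates <- count_breakpoints(rearrs, bins, dedup = FALSE)
  bg <- fit_juxtaposition_background(rearrs, break_rates, bins,
                                     min_event_size = min_event_size, ...)
  ev <- count_tile_events(rearrs, bins, min_event_size)
  n_events <- attr(ev, "n_events")
  ne <- sum(bg$exposure)
  m <- ne * (ne + 1) / 2                     # tiles with nonzero exposure
  p0 <- bg$p0[cbind(ev$i, ev$j)]
  ok <- p0 > 0
  ev <- ev[ok, ]; p0 <- p0[ok]
  p <- srj_test(ev$observed, n_events, p0)
  ## BH over the full universe: zero-event tiles all carry p = 1
  q <- bh_with_unit_block(p, m)
  expected <- n_events * p0
  alpha_tile <- if (any(q < q_threshold)) max(p[q < q_threshold]) else NA
  rf <- rep(NA_real_, length(p))
  sig <- which(!is.na(alpha_tile) & q < q_threshold)
  for (k in sig)
    rf[k] <- robustness_factor(ev$observed[k], n_events, p0[k], alpha_tile)
  tiles <- data.frame(
    chrom_i = bins$chrom[ev$i], start_i = bins$start[ev$i],
    chrom_j = bins$chrom[ev$j], start_j = bins$start[ev$j],
    bin_i = ev$i, bin_j = ev$j,
    observed = ev$observed, expected = expected, p0 = p0,
    p = p, q = q, effect_size = effect_size(ev$observed, expected),
    robustness_factor = rf,
    intra = bins$chrom[ev$i] == bins$chrom[ev$j],
    stringsAsFactors = FALSE)
  tiles <- tiles[order(tiles$p), ]
  rownames(tiles) <- NULL
  list(tiles = tiles, background = bg, n_events = n_events, m = m,
       alpha_tile = alpha_tile)
}

## weighted pool-adjacent-violators, non-increasing fit
pava_decreasing <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; idx <- as.list(seq_len(n))
  i <- 1
  while (i < length(val)) {
    if (val[i] >= val[i + 1] - 1e-15) { i <- i + 1; next }
    nv <- (val[i] * wt[i] + val[i + 1] * wt[i + 1]) / (wt[i] + wt[i + 1])
    val[i] <- nv; wt[i] <- wt[i] + wt[i + 1]
    idx[[i]] <- c(idx[[i]], idx[[i + 1]])
    val <- val[-(i + 1)]; wt <- wt[-(i + 1)]; idx <- idx[-(i + 1)]
    if (i > 1) i <- i - 1
  }
  out <- numeric(n)
  for (j in seq_along(val)) out[idx[[j]]] <- val[j]
  out
}

## BH step-up over a universe of size m of which only the supplied p's are
## below 1; the remaining m - length(p) hypotheses have p = 1 analytically.
bh_with_unit_block <- function(p, m) {
  k <- length(p)
  if (!k) return(numeric(0))
  if (m < k) stop("universe smaller than number of tested hypotheses")
  o <- order(p)
  ranked <- p[o] * m / seq_len(k)
  ## hypotheses with p = 1 occupy ranks k+1..m: candidate q there is
  ## m * 1 / j >= 1, so the running minimum from above starts at 1
  q_sorted <- pmin(rev(cummin(rev(ranked))), 1)
  q <- numeric(k)
  q[o] <- q_sorted
  q
}
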