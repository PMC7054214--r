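#' Define a genome as an ordered set of chromosomes
#'
#' All coordinates in the package are 0-based half-open (BED/BEDPE native).
#'
#' @param chrom_names Character vector of unique chromosome names, in order.
#' @param chrom_lengths Numeric vector of chromosome lengths in bp (> 0).
#' @return An object of class `genome_def` with fields `chrom` and `length`
#'   (named by chromosome).
#' @examples
#' g <- genome_def(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_def <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths must have equal length")
  if (anyDuplicated(chrom_names))
    stop("chromosome names must be unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive and finite")
  structure(
    list(chrom = chrom_names,
         length = stats::setNames(chrom_lengths, chrom_names)),
    class = "genome_def")
}

#' @export
print.genome_def <- function(x, ...) {
  cat(sprintf("<genome_def> %d chromosomes, %.3f Mb total\n",
              length(x$chrom), sum(x$length) / 1e6))
  invisible(x)
}

#' Tile a genome into fixed-width bins
#'
#' Bins tile each chromosome left to right; the last bin of a chromosome may
#' be shorter than `width`. Every genomic position belongs to exactly one
#' bin. When a mappability track is supplied, `eligible` holds the number of
#' mappable bases per bin (the exposure used by the breakpoint background
#' model); otherwise every base is eligible.
#'
#' @param genome A [genome_def()].
#' @param width Bin width in bp (default 100 kb, the tile size used for
#'   juxtaposition testing).
#' @param mappability Optional covariate track (see [read_track()]) whose
#'   `value` is the mappable fraction of each bin, in the same bin order.
#' @return A data.frame of class `genomic_bins` with columns `chrom`,
#'   `start`, `end`, `eligible`; bin width and genome are kept as attributes.
#' @export
make_bins <- function(genome, width = 1e5, mappability = NULL) {
  stopifnot(inherits(genome, "genome_def"))
  if (!is.numeric(width) || length(width) != 1 || width <= 0)
    stop("width must be a positive number")
  pieces <- lapply(genome$chrom, function(cn) {
    len <- genome$length[[cn]]
    starts <- seq(0, len - 1, by = width)
    ends <- pmin(starts + width, len)
    data.frame(chrom = cn, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$eligible <- bins$end - bins$start
  if (!is.null(mappability)) {
    frac <- mappability$value
    if (length(frac) != nrow(bins))
      stop("mappability track has ", length(frac), " values but there are ",
           nrow(bins), " bins")
    frac[is.na(frac)] <- 0
    frac <- pmin(pmax(frac, 0), 1)
    bins$eligible <- (bins$end - bins$start) * frac
  }
  structure(bins, class = c("genomic_bins", "data.frame"),
            width = width, genome = genome)
}

#' Map genomic positions to bin indices
#'
#' @param bins Bins from [make_bins()].
#' @param chrom,pos Vectors of chromosome names and 0-based positions.
#' @return Integer row indices into `bins`; NA where the chromosome is not
#'   part of the binned genome or the position is out of range.
#' @export
bin_index <- function(bins, chrom, pos) {
  genome <- attr(bins, "genome")
  width <- attr(bins, "width")
  # bins are stored chromosome-major; offset of each chromosome's first bin
  nbin_per <- ceiling(genome$length / width)
  offset <- stats::setNames(cumsum(c(0, nbin_per[-length(nbin_per)])),
                            genome$chrom)
  idx <- rep(NA_integer_, length(chrom))
  known <- chrom %in% genome$chrom
  inrange <- known & pos >= 0 & pos < genome$length[
    ifelse(known, chrom, genome$chrom[1])]
  ok <- which(known & inrange)
  if (length(ok))
    idx[ok] <- as.integer(offset[chrom[ok]] + pos[ok] %/% width + 1)
  idx
}

## coordinate conversions: internal representation is 0-based half-open.
## to_one_based/to_zero_based are mutual inverses on positions.

#' Convert between 0-based half-open and 1-based inclusive positions
#'
#' @param pos Numeric vector of positions.
#' @return Converted positions.
#' @export
to_one_based <- function(pos) pos + 1

#' @rdname to_one_based
#' @export
to_zero_based <- function(pos) pos - 1
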