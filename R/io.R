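## Readers/writers for the external formats the toolkit touches: BEDPE
## (rearrangements), BED (elements), bedGraph-like TSV (covariate tracks),
## MAF-like TSV (mutations), and generic result tables. All coordinates are
## held 0-based half-open internally.

#' Read somatic rearrangements from a BEDPE file
#'
#' Expects the standard 10-column BEDPE dialect (chrom1, start1, end1,
#' chrom2, start2, end2, name, score, strand1, strand2). The breakpoint
#' position of each end is the lower coordinate of the end interval. Records
#' are canonicalized so that breakpoint 1 precedes breakpoint 2 in genome
#' order (chromosome order of `genome`, then position). The sample ID is
#' taken from the `name` column unless `sample_col` names another column.
#' Rows on chromosomes absent from `genome` (decoys, unplaced contigs) are
#' skipped with a warning carrying the count.
#'
#' @param path Path to a BEDPE file (plain text, tab-separated, optional
#'   header line starting with `#`).
#' @param genome A [genome_def()] used to validate chromosomes and order
#'   breakpoints.
#' @param sample_col Column (number or name) carrying the sample ID;
#'   default the BEDPE `name` column (7).
#' @param sv_class_col Optional column carrying the SV class
#'   (DEL/DUP/INV/TRA); classes outside that set become "unknown".
#' @return A data.frame of class `rearrangements` with columns `chrom1`,
#'   `pos1`, `chrom2`, `pos2`, `sample`, `sv_class`, `strand1`, `strand2`.
#'   The number of skipped rows is kept in attribute `n_skipped`.
#' @export
read_bedpe <- function(path, genome, sample_col = 7, sv_class_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    out <- rearrangements(character(0), numeric(0), character(0), numeric(0),
                          character(0), character(0), genome = genome)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 10)
  if (length(bad))
    stop("malformed BEDPE row (fewer than 10 columns) at line ", bad[1])
  get <- function(i) vapply(fields, `[[`, "", i)
  col_idx <- function(col) if (is.character(col)) stop(
    "named columns require a header; use a column number") else as.integer(col)
  chrom1 <- get(1); chrom2 <- get(4)
  pos1 <- suppressWarnings(as.numeric(get(2)))
  pos2 <- suppressWarnings(as.numeric(get(5)))
  if (anyNA(pos1) || anyNA(pos2))
    stop("malformed BEDPE row (non-numeric coordinate) at line ",
         which(is.na(pos1) | is.na(pos2))[1])
  sample <- get(col_idx(sample_col))
  sv_class <- if (is.null(sv_class_col)) rep("unknown", length(lines))
              else get(col_idx(sv_class_col))
  sv_class[!sv_class %in% c("DEL", "DUP", "INV", "TRA")] <- "unknown"
  strand1 <- get(9); strand2 <- get(10)

  known <- chrom1 %in% genome$chrom & chrom2 %in% genome$chrom
  n_skipped <- sum(!known)
  if (n_skipped > 0)
    warning(n_skipped, " rearrangement(s) on unknown chromosomes skipped")
  out <- rearrangements(chrom1[known], pos1[known], chrom2[known],
                        pos2[known], sample[known], sv_class[known],
                        strand1 = strand1[known], strand2 = strand2[known],
                        genome = genome)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Construct a canonicalized rearrangement table
#'
#' Breakpoint pairs are ordered so bp1 <= bp2 in genome order. Used by
#' [read_bedpe()] and the simulator.
#'
#' @param chrom1,pos1,chrom2,pos2 Breakpoint coordinates (0-based).
#' @param sample Sample IDs (non-empty).
#' @param sv_class SV classes; coerced to DEL/DUP/INV/TRA/unknown.
#' @param strand1,strand2 Optional orientations (kept, unused by statistics).
#' @param genome A [genome_def()].
#' @return data.frame of class `rearrangements`.
#' @export
rearrangements <- function(chrom1, pos1, chrom2, pos2, sample,
                           sv_class = "unknown",
                           strand1 = "*", strand2 = "*", genome) {
  n <- length(chrom1)
  if (n && any(!nzchar(sample))) stop("sample IDs must be non-empty")
  df <- data.frame(chrom1 = as.character(chrom1), pos1 = as.numeric(pos1),
                   chrom2 = as.character(chrom2), pos2 = as.numeric(pos2),
                   sample = as.character(sample),
                   sv_class = rep_len(as.character(sv_class), n),
                   strand1 = rep_len(as.character(strand1), n),
                   strand2 = rep_len(as.character(strand2), n),
                   stringsAsFactors = FALSE)
  if (n) {
    ord1 <- match(df$chrom1, genome$chrom)
    ord2 <- match(df$chrom2, genome$chrom)
    flip <- ord2 < ord1 | (ord2 == ord1 & df$pos2 < df$pos1)
    if (any(flip)) {
      tmp <- df[flip, c("chrom1", "pos1", "strand1")]
      df[flip, c("chrom1", "pos1", "strand1")] <-
        df[flip, c("chrom2", "pos2", "strand2")]
      df[flip, c("chrom2", "pos2", "strand2")] <- tmp
    }
  }
  structure(df, class = c("rearrangements", "data.frame"), genome = genome)
}

#' Read somatic mutations from a MAF-like tab-separated table
#'
#' Required header columns: `chrom`, `pos`, `ref`, `alt`, `sample`. Optional
#' columns: `in_mappable`, `in_palindrome` (0/1 or TRUE/FALSE) and any
#' number of signature-attribution columns named `sig_<name>` with
#' per-mutation probabilities in `[0, 1]`. The variant type and indel length
#' are derived from the allele lengths (`-` or empty treated as length 0).
#'
#' @param path Path to the TSV file.
#' @param one_based Set TRUE if positions are 1-based inclusive (explicit
#'   conversion to the internal 0-based convention; never silent).
#' @return data.frame of class `mutations` with `chrom`, `pos`, `ref`,
#'   `alt`, `sample`, `var_type` (SNV/INS/DEL/MNV), `indel_length`, plus any
#'   annotation columns present.
#' @export
read_mutations <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "sample")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("mutation table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  df$pos <- as.numeric(df$pos)
  if (one_based) df$pos <- to_zero_based(df$pos)
  annotate_mutations(df)
}

## derive var_type / indel_length from allele lengths; shared with simulator
annotate_mutations <- function(df) {
  alen <- function(a) { a <- as.character(a); a[a == "-" | is.na(a)] <- ""; nchar(a) }
  rl <- alen(df$ref); al <- alen(df$alt)
  df$var_type <- ifelse(rl == 1 & al == 1, "SNV",
                 ifelse(al > rl, "INS", ifelse(rl > al, "DEL", "MNV")))
  df$indel_length <- abs(rl - al)
  for (col in c("in_mappable", "in_palindrome"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]] %in%
                                                    c(TRUE, 1, "1", "TRUE"))
  sig_cols <- grep("^sig_", names(df), value = TRUE)
  for (col in sig_cols) {
    v <- as.numeric(df[[col]])
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop("signature fractions in ", col, " must lie in [0, 1]")
    df[[col]] <- v
  }
  structure(df, class = c("mutations", "data.frame"))
}

#' Read genomic elements from a BED file
#'
#' BED4 (chrom, start, end, id); multiple rows with the same id form one
#' multi-interval element. Overlapping or book-ended intervals of the same
#' element are merged (normalization is idempotent); `total_length` is the
#' summed interval length after merging. An optional 5th column carries the
#' element type.
#'
#' @param path Path to a BED file.
#' @return data.frame of class `elements` with columns `id`, `chrom`,
#'   `start`, `end`, `element_type`; per-id total lengths in attribute
#'   `total_length`.
#' @export
read_elements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines))
    return(normalize_elements(data.frame(id = character(0),
      chrom = character(0), start = numeric(0), end = numeric(0),
      element_type = character(0), stringsAsFactors = FALSE)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4))
    stop("BED element rows need at least 4 columns (chrom start end id); ",
         "first bad line: ", which(lengths(fields) < 4)[1])
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1),
    start = as.numeric(vapply(fields, `[[`, "", 2)),
    end = as.numeric(vapply(fields, `[[`, "", 3)),
    id = vapply(fields, `[[`, "", 4),
    element_type = vapply(fields, function(f)
      if (length(f) >= 5) f[[5]] else "custom", ""),
    stringsAsFactors = FALSE)
  normalize_elements(df)
}

#' Normalize an element table (merge overlapping intervals per id)
#'
#' @param df data.frame with `id`, `chrom`, `start`, `end` and optionally
#'   `element_type`.
#' @return data.frame of class `elements`; see [read_elements()].
#' @export
normalize_elements <- function(df) {
  if (is.null(df$element_type)) df$element_type <- "custom"
  if (nrow(df) && any(df$end <= df$start))
    stop("element intervals must satisfy start < end")
  pieces <- split(df, df$id)
  merged <- lapply(pieces, function(e) {
    out <- do.call(rbind, lapply(split(e, e$chrom), function(ec) {
      ec <- ec[order(ec$start), , drop = FALSE]
      ms <- ec$start[1]; me <- ec$end[1]; keep <- list()
      for (i in seq_len(nrow(ec))[-1]) {
        if (ec$start[i] <= me) me <- max(me, ec$end[i])
        else { keep[[length(keep) + 1]] <- c(ms, me); ms <- ec$start[i]; me <- ec$end[i] }
      }
      keep[[length(keep) + 1]] <- c(ms, me)
      k <- do.call(rbind, keep)
      data.frame(id = ec$id[1], chrom = ec$chrom[1], start = k[, 1],
                 end = k[, 2], element_type = ec$element_type[1],
                 stringsAsFactors = FALSE)
    }))
    out
  })
  out <- do.call(rbind, c(merged, list(make.row.names = FALSE)))
  if (is.null(out)) out <- df[, c("id", "chrom", "start", "end", "element_type")]
  rownames(out) <- NULL
  tl <- vapply(split(out$end - out$start, out$id), sum, 0)
  structure(out, class = c("elements", "data.frame"), total_length = tl)
}

#' Read a per-bin covariate track from a bedGraph-like TSV
#'
#' Four columns (chrom, start, end, value), no header. Values are averaged
#' (length-weighted) over each genome bin; bins with no covering interval
#' are NA (the missing-value mask).
#'
#' @param path Path to the track file.
#' @param genome A [genome_def()].
#' @param width Bin width in bp.
#' @param name Track name.
#' @return data.frame of class `covariate_track` with one `value` per bin.
#' @export
read_track <- function(path, genome, width = 1e5, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("track file needs 4 columns (chrom start end value)")
  names(df)[1:4] <- c("chrom", "start", "end", "value")
  bins <- make_bins(genome, width)
  val <- rep(NA_real_, nrow(bins)); wt <- rep(0, nrow(bins))
  acc <- rep(0, nrow(bins))
  for (i in seq_len(nrow(df))) {
    s <- df$start[i]; e <- df$end[i]
    if (!df$chrom[i] %in% genome$chrom) next
    b0 <- bin_index(bins, df$chrom[i], s)
    b1 <- bin_index(bins, df$chrom[i], e - 1)
    for (b in b0:b1) {
      ov <- min(e, bins$end[b]) - max(s, bins$start[b])
      if (ov > 0) { acc[b] <- acc[b] + ov * df$value[i]; wt[b] <- wt[b] + ov }
    }
  }
  val[wt > 0] <- acc[wt > 0] / wt[wt > 0]
  covariate_track(name, val)
}

#' Construct a covariate track aligned to a binning
#'
#' @param name Track name.
#' @param value Numeric vector, one value per bin; NA marks missing bins.
#' @return data.frame of class `covariate_track`.
#' @export
covariate_track <- function(name, value) {
  if (any(!is.finite(value) & !is.na(value)))
    stop("track values must be finite where not missing")
  structure(data.frame(value = as.numeric(value)),
            class = c("covariate_track", "data.frame"), name = name)
}

#' Write / read a result table (TSV with header)
#'
#' Round-trip stable: text columns bit-exact, numeric columns to full
#' double precision (15 significant digits).
#'
#' @param results A data.frame.
#' @param path Output path.
#' @return `write_results` returns `path` invisibly; `read_results` a
#'   data.frame.
#' @export
write_results <- function(results, path) {
  df <- as.data.frame(results)
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) df[[j]] <- formatC(df[[j]], digits = 15, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
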