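## Hotspot tabulation and localized mutational-process diagnostics:
## per-position distinct-patient SNV counts, and the 2-5-bp indel
## enrichment and indel-rate binomial screens used to recognize
## transcription-associated indel processes.

#' Tabulate SNV hotspots by distinct patient count
#'
#' Counts distinct patients per genomic position (SNVs only; a sample
#' mutated twice at one position counts once) and ranks positions by
#' count, ties broken by genome order. Either the top `top_k` positions
#' or all positions reaching `min_fraction` of patients are returned.
#'
#' @param mutations A `mutations` table.
#' @param top_k Number of hotspots to keep (default 50).
#' @param min_fraction Alternative to `top_k`: keep positions mutated in
#'   at least this fraction of patients.
#' @param genome Optional [genome_def()] fixing chromosome order for tie
#'   breaking (default: alphabetical).
#' @return data.frame: chrom, pos, ref, alt, n_patients, fraction.
#' @export
find_hotspots <- function(mutations, top_k = 50, min_fraction = NULL,
                          genome = NULL) {
  snv <- mutations[mutations$var_type == "SNV", , drop = FALSE]
  n_cohort <- length(unique(mutations$sample))
  if (!nrow(snv))
    return(data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0),
                      n_patients = integer(0), fraction = numeric(0)))
  key <- paste0(snv$chrom, "\r", snv$pos)
  dedup <- snv[!duplicated(paste0(key, "\r", snv$sample)), , drop = FALSE]
  key2 <- paste0(dedup$chrom, "\r", dedup$pos)
  tab <- table(key2)
  first <- dedup[!duplicated(key2), , drop = FALSE]
  first <- first[match(names(tab), paste0(first$chrom, "\r", first$pos)), ]
  out <- data.frame(chrom = first$chrom, pos = first$pos, ref = first$ref,
                    alt = first$alt, n_patients = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$fraction <- out$n_patients / n_cohort
  chrom_rank <- if (is.null(genome)) match(out$chrom, sort(unique(out$chrom)))
                else match(out$chrom, genome$chrom)
  out <- out[order(-out$n_patients, chrom_rank, out$pos), ]
  rownames(out) <- NULL
  if (!is.null(min_fraction)) out[out$fraction >= min_fraction, ]
  else utils::head(out, top_k)
}

#' 2-5-bp indel enrichment per gene
#'
#' For each gene, the proportion of its indels with length 2-5 bp
#' (inclusive) is compared to the background proportion by a one-sided
#' binomial test, p = P(X >= observed | n_total, background). The
#' background is computed from all other genes' indels in the same cohort
#' (self excluded) unless supplied. Genes with zero indels are flagged
#' not evaluable. q-values by BH within this test family.
#'
#' @param gene Per-indel gene IDs.
#' @param indel_length Per-indel lengths in bp (>= 1).
#' @param background Optional fixed background proportion in (0, 1).
#' @param q_threshold Enrichment call threshold on q (default 0.1).
#' @return data.frame per gene: n_indels, n_2_5, background, p, q,
#'   enriched.
#' @export
indel_size_enrichment <- function(gene, indel_length, background = NULL,
                                  q_threshold = 0.1) {
  stopifnot(length(gene) == length(indel_length))
  if (any(indel_length < 1)) stop("indel lengths must be >= 1")
  in25 <- indel_length >= 2 & indel_length <= 5
  n_tot <- tapply(rep(1, length(gene)), gene, sum)
  n_25 <- tapply(as.numeric(in25), gene, sum)
  genes <- names(n_tot)
  bg <- if (!is.null(background)) {
    stopifnot(background > 0, background < 1)
    rep(background, length(genes))
  } else {
    tot_all <- length(gene); tot_25 <- sum(in25)
    vapply(genes, function(g)
      (tot_25 - n_25[[g]]) / max(tot_all - n_tot[[g]], 1), 0)
  }
  bg <- pmin(pmax(bg, 1e-12), 1 - 1e-12)
  p <- binom_tail(n_25, n_tot, bg)
  out <- data.frame(gene = genes, n_indels = as.integer(n_tot),
                    n_2_5 = as.integer(n_25), background = bg, p = p,
                    q = benjamini_hochberg(p), stringsAsFactors = FALSE)
  out$enriched <- out$q < q_threshold
  rownames(out) <- NULL
  out
}

#' Indel rate test per gene
#'
#' Compares each gene's total indel count (regardless of length) to the
#' length-scaled background expectation: one-sided binomial with n =
#' total indels over all genes and per-gene probability equal to the
#' gene's share of the total tested length. q-values by BH within this
#' family (separate from the size test).
#'
#' @param gene Gene IDs (one per tested gene).
#' @param n_indels Indel count per gene.
#' @param length_bp Gene length per gene.
#' @param q_threshold Call threshold on q (default 0.1).
#' @return data.frame per gene: n_indels, expected, p, q, elevated.
#' @export
indel_rate_test <- function(gene, n_indels, length_bp, q_threshold = 0.1) {
  stopifnot(length(gene) == length(n_indels),
            length(gene) == length(length_bp))
  n_total <- sum(n_indels)
  p0 <- length_bp / sum(length_bp)
  p <- binom_tail(n_indels, n_total, p0)
  out <- data.frame(gene = gene, n_indels = n_indels,
                    expected = n_total * p0, p = p,
                    q = benjamini_hochberg(p), stringsAsFactors = FALSE)
  out$elevated <- out$q < q_threshold
  out
}
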