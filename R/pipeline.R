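## End-to-end orchestration: simulate inputs, run the SRB/SRJ scans, the
## p-value integration with post-filters, power and excess summaries, and
## write stage outputs plus a run manifest.

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; unknown keys are
#' rejected. All analysis thresholds (q cutoffs, filter fractions,
#' calibration bounds, bin widths) can be set here.
#'
#' @param path Path to a YAML file.
#' @return A [sim_config()] plus any threshold overrides in attribute
#'   `thresholds`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  thr_keys <- c("q_threshold", "near_threshold", "d_thresh",
                "min_event_size", "min_eligible_frac", "lambda_bounds",
                "ks_max", "window_width", "alpha_global")
  unknown <- setdiff(names(raw), c(known, thr_keys))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  ## spike tables arrive as YAML sequences of mappings
  for (key in c("srb_spikes", "srj_spikes"))
    if (!is.null(raw[[key]]) && !is.data.frame(raw[[key]]))
      raw[[key]] <- do.call(rbind, lapply(raw[[key]], as.data.frame))
  cfg <- do.call(sim_config, raw[intersect(names(raw), known)])
  attr(cfg, "thresholds") <- raw[intersect(names(raw), thr_keys)]
  cfg
}

#' Run the full driver-discovery pipeline on simulated inputs
#'
#' Stages: simulate rearrangements and mutations, SRB scan, SRJ scan,
#' Brown combination + tiers + post-filters of the simulated method
#' p-value matrix, a small power grid, and the excess-mutation estimate
#' for the planted driver elements. Each stage writes a TSV into
#' `out_dir`; a JSON manifest (config snapshot, seed, package version,
#' per-stage row counts, output checksums) and a human-readable summary
#' are written alongside. A stage failure aborts with the stage name;
#' outputs of completed stages are preserved.
#'
#' @param config A [sim_config()] (or path to a YAML accepted by
#'   [read_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  results <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    results[[name]] <<- res
    res
  }

  sim <- stage("simulate_sv", simulate_rearrangements(config))
  write_results(as.data.frame(sim$rearrs),
                file.path(out_dir, "rearrangements.tsv"))
  counts$rearrangements <- nrow(sim$rearrs)

  srb <- stage("srb", srb_scan(sim$rearrs, sim$bins,
                               covariates = sim$covariates,
                               rep_timing = sim$covariates$timing))
  write_results(srb$bins, file.path(out_dir, "srb_bins.tsv"))
  write_results(srb$loci[, setdiff(names(srb$loci), "bin_idx")],
                file.path(out_dir, "srb_loci.tsv"))
  counts$srb_loci <- nrow(srb$loci)

  srj <- stage("srj", srj_scan(sim$rearrs, sim$bins,
                               break_rates = srb$model$mu))
  write_results(srj$tiles, file.path(out_dir, "srj_tiles.tsv"))
  counts$srj_tiles_significant <- sum(srj$tiles$q < 0.1)

  msim <- stage("simulate_mutations", simulate_mutations(config))
  write_results(msim$mutations, file.path(out_dir, "mutations.tsv"))
  counts$mutations <- nrow(msim$mutations)

  psim <- stage("simulate_pvalues", simulate_pvalue_matrix(config))
  ledger <- stage("integrate", {
    calib <- calibrate_methods(psim$pmat, min_rows = 20)
    keep <- calib$method[calib$keep]
    pm <- psim$pmat
    pm$p <- pm$p[, keep, drop = FALSE]
    ## mutation-level annotations for the post-filters: mutations of the
    ## matching simulated element, whichever cohort the row is from
    el <- msim$elements
    mut_elem <- rep(NA_character_, nrow(msim$mutations))
    for (i in seq_len(nrow(el))) {
      inel <- msim$mutations$chrom == el$chrom[i] &
        msim$mutations$pos >= el$start[i] & msim$mutations$pos < el$end[i]
      mut_elem[inel] <- el$id[i]
    }
    by_key <- list()
    for (k in seq_along(pm$element)) {
      key <- paste(pm$cohort[k], pm$element[k], sep = ":")
      by_key[[key]] <- msim$mutations[!is.na(mut_elem) &
                                        mut_elem == pm$element[k], ,
                                      drop = FALSE]
    }
    candidate_ledger(pm, by_key,
                     cohort_types = stats::setNames(
                       rep(config$cohort_type, 2),
                       c("cohortA", "cohortB")))
  })
  write_results(ledger, file.path(out_dir, "candidate_ledger.tsv"))
  counts$candidates_significant <-
    sum(ledger$final_status == "significant")

  pw <- stage("power", power_grid(
    n_patients = c(100, 500, 2500), bg_rate = c(1e-7, 1e-6),
    length_bp = 1000, sensitivity = c(0.5, 1), n_tests = 1000))
  write_results(pw, file.path(out_dir, "power_grid.tsv"))

  exc <- stage("excess", {
    scan <- window_scan(msim$mutations, msim$genome, width = 2000)
    drv <- msim$truth$element
    erow <- msim$elements[msim$elements$id %in% drv, , drop = FALSE]
    if (nrow(erow)) {
      idx <- !is.na(bin_index_elements(scan$windows, erow))
      obs <- sum(scan$windows$observed[idx])
      exp_ <- sum(scan$windows$expected[idx])
      excess_mutations(obs, exp_)
    } else excess_mutations(0, 0)
  })
  write_results(exc, file.path(out_dir, "excess.tsv"))

  outputs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    tool = "svdriverscan",
    version = as.character(utils::packageVersion("svdriverscan")),
    seed = config$seed,
    config = config[setdiff(names(config), "")],
    stage_counts = counts,
    checksums = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  summary_lines <- c(
    sprintf("svdriverscan run, seed %d", config$seed),
    sprintf("rearrangements: %d", counts$rearrangements),
    sprintf("SRB loci (Q < 0.1): %d", counts$srb_loci),
    sprintf("SRJ tiles (Q < 0.1): %d", counts$srj_tiles_significant),
    sprintf("mutations: %d", counts$mutations),
    sprintf("significant candidates after filtering: %d",
            counts$candidates_significant))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(c(results, list(manifest = manifest)))
}

## rows of `windows` covered by any interval of `elements`: returns the
## window's element id or NA
bin_index_elements <- function(windows, elements) {
  hit <- rep(NA_character_, nrow(windows))
  for (i in seq_len(nrow(elements))) {
    ov <- windows$chrom == elements$chrom[i] &
      windows$start < elements$end[i] & windows$end > elements$start[i]
    hit[ov] <- elements$id[i]
  }
  hit
}
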