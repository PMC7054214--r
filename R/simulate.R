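## Fixture generator: produces every input the toolkit consumes
## (rearrangements, covariate tracks, mutations, elements, per-method
## p-value matrices) from the generative assumptions the tests invert
## (Gamma-Poisson breakpoint counts over covariates, mixture
## juxtaposition placement with a distance kernel, Poisson passenger
## mutations with spiked driver elements, Gaussian-copula method
## p-values), with a truth table for every planted driver.

#' Simulation configuration
#'
#' All rates are per the units named; unset fields take the defaults,
#' which describe a 200-sample cohort over a 60-Mb three-chromosome
#' genome binned at 100 kb, with rearrangement and mutation densities
#' scaled from typical whole-genome cohorts.
#'
#' @param seed Mandatory RNG seed.
#' @param n_chrom,chrom_length,bin_width Genome model.
#' @param eligible_frac Mappable fraction per bin (scalar).
#' @param covariate_effects Named log-scale effects of the generated
#'   covariate tracks (`timing` in `[0, 1]`, `gc` standardized).
#' @param alpha Gamma-Poisson overdispersion of breakpoint counts.
#' @param n_samples Cohort size.
#' @param rearr_per_sample Mean rearrangements per sample (Poisson).
#' @param mixture_w Weight of the two-independent-breaks component of
#'   juxtaposition placement; 1 - w is the distance-kernel (invasion)
#'   component.
#' @param kernel_exponent Pareto tail exponent of the invasion distance
#'   kernel.
#' @param srb_spikes data.frame of planted SRB loci with columns `bin`,
#'   `regime` ("clustered": all partners in one bin, fusion-like;
#'   "dispersed"), and either `frequency` (fraction of samples receiving
#'   one breakpoint in the bin) or `fold` (target fold-enrichment over
#'   the bin's systematic background rate, floored at `spike_min_freq`
#'   of the cohort).
#' @param spike_min_freq Minimum fraction of samples carrying a planted
#'   breakpoint when spikes are given as fold-enrichments (default 0.03).
#' @param srj_spikes data.frame(bin_i, bin_j, frequency) of planted
#'   juxtapositions.
#' @param n_elements,element_length,mut_rate Mutation-side genome:
#'   element count, length (bp), passenger rate per bp per sample.
#' @param element_spacing Grid pitch as a multiple of `element_length`
#'   (1 = elements tile the region contiguously; default 4).
#' @param mut_rate_sd Log-normal sd of a per-element local-rate
#'   multiplier (0 = homogeneous); its log is returned as the
#'   `local_rate` covariate of the elements, mirroring the local
#'   mutation-rate track a burden model would use.
#' @param driver_elements Indices of elements receiving driver mutations.
#' @param driver_frequency Fraction of patients mutated in each driver
#'   element.
#' @param indel_frac Fraction of mutations that are indels.
#' @param indel_size_2_5_frac Background proportion of indels with length
#'   2-5 bp.
#' @param cohort_type "lymphoid", "melanoma" or "other" (sets the
#'   signature mixture).
#' @param sig_profile Named attribution probabilities over signatures
#'   (apobec, aid, uv, other); default depends on `cohort_type`.
#' @param mappable_frac,palindrome_frac Bernoulli rates of the mutation
#'   annotation flags.
#' @param n_rows,n_methods,rho,gamma_distortion,missing_frac,
#'   n_driver_rows,driver_strength P-value-matrix generator: row/method
#'   counts, copula correlation, per-method distortion exponents
#'   (p -> p^gamma), missingness, planted driver rows (their p scaled
#'   down multiplicatively by `driver_strength`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chrom = 3, chrom_length = 2e7, bin_width = 1e5,
                       eligible_frac = 1,
                       covariate_effects = c(timing = 0.8, gc = -0.3),
                       alpha = 0.15,
                       n_samples = 200, rearr_per_sample = 2,
                       mixture_w = 0.4, kernel_exponent = 0.8,
                       srb_spikes = NULL, srj_spikes = NULL,
                       spike_min_freq = 0.03,
                       n_elements = 300, element_length = 1000,
                       element_spacing = 4, mut_rate = 2e-6,
                       mut_rate_sd = 0,
                       driver_elements = integer(0),
                       driver_frequency = 0.1,
                       indel_frac = 0.1, indel_size_2_5_frac = 0.3,
                       cohort_type = "other", sig_profile = NULL,
                       mappable_frac = 0.95, palindrome_frac = 0.05,
                       n_rows = 1000, n_methods = 6, rho = 0.3,
                       gamma_distortion = NULL, missing_frac = 0,
                       n_driver_rows = 0, driver_strength = 1e-4) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(sig_profile))
    sig_profile <- switch(cohort_type,
      lymphoid = c(apobec = 0.1, aid = 0.45, uv = 0.01, other = 0.44),
      melanoma = c(apobec = 0.05, aid = 0.01, uv = 0.6, other = 0.34),
      c(apobec = 0.15, aid = 0.02, uv = 0.02, other = 0.81))
  if (is.null(gamma_distortion)) gamma_distortion <- rep(1, n_methods)
  cfg <- as.list(environment())
  stopifnot(all(vapply(cfg[c("alpha", "rearr_per_sample", "mut_rate",
                             "driver_frequency")], `>=`, TRUE, 0)))
  structure(cfg, class = "sim_config")
}

sim_genome <- function(config) {
  genome_def(paste0("chr", seq_len(config$n_chrom)),
             rep(config$chrom_length, config$n_chrom))
}

## smooth per-bin covariate tracks: replication timing in [0, 1] and a
## standardized GC-like track
sim_covariates <- function(nbins) {
  smooth <- function(x, k = 9) {
    y <- stats::filter(x, rep(1 / k, k), circular = TRUE)
    as.numeric(y)
  }
  timing <- smooth(stats::runif(nbins))
  timing <- (timing - min(timing)) / (max(timing) - min(timing) + 1e-12)
  gc <- smooth(stats::rnorm(nbins))
  gc <- (gc - mean(gc)) / stats::sd(gc)
  list(timing = covariate_track("timing", timing),
       gc = covariate_track("gc", gc))
}

#' Simulate somatic rearrangements with known ground truth
#'
#' Breakpoint intensity per bin follows the Gamma-Poisson background
#' (covariate log-linear mean times a gamma multiplier with the
#' configured overdispersion); each rearrangement's first breakpoint is
#' placed by that intensity and its partner either independently (weight
#' `mixture_w`) or at a Pareto-distributed distance (invasion). Planted
#' SRB loci and SRJ pairs are overlaid on the configured fractions of
#' samples.
#'
#' @param config A [sim_config()].
#' @return List: `rearrs`, `bins`, `genome`, `covariates` (timing, gc),
#'   `truth` (data.frames `srb` and `srj` of planted drivers), `config`.
#' @export
simulate_rearrangements <- function(config) {
  set.seed(config$seed)
  genome <- sim_genome(config)
  bins <- make_bins(genome, config$bin_width)
  bins$eligible <- bins$eligible * config$eligible_frac
  nb <- nrow(bins)
  cov <- sim_covariates(nb)
  eff <- config$covariate_effects
  lin <- eff[["timing"]] * cov$timing$value + eff[["gc"]] * cov$gc$value
  lambda <- exp(lin) * bins$eligible
  gm <- if (config$alpha > 0)
    stats::rgamma(nb, shape = 1 / config$alpha, rate = 1 / config$alpha)
  else rep(1, nb)
  intensity <- lambda * gm

  n_s <- stats::rpois(config$n_samples, config$rearr_per_sample)
  total <- sum(n_s)
  samples <- rep(sprintf("s%04d", seq_len(config$n_samples)), n_s)

  rpos <- function(b) bins$start[b] +
    floor(stats::runif(length(b)) * (bins$end[b] - bins$start[b]))
  empty <- data.frame(chrom1 = character(0), pos1 = numeric(0),
                      chrom2 = character(0), pos2 = numeric(0),
                      sample = character(0))
  if (total > 0) {
    b1 <- sample.int(nb, total, replace = TRUE, prob = intensity)
    pos1 <- rpos(b1)
    chrom1 <- bins$chrom[b1]
    two_break <- stats::runif(total) < config$mixture_w
    b2 <- integer(total); pos2 <- numeric(total)
    n2b <- sum(two_break)
    if (n2b) {
      b2[two_break] <- sample.int(nb, n2b, replace = TRUE, prob = intensity)
      pos2[two_break] <- rpos(b2[two_break])
    }
    inv <- which(!two_break)
    if (length(inv)) {
      ## invasion distance: Pareto truncated to the feasible range of the
      ## chosen direction, so no mass piles up at chromosome ends
      len <- genome$length[chrom1[inv]]
      sgn <- sample(c(-1, 1), length(inv), replace = TRUE)
      reach <- ifelse(sgn > 0, len - 1 - pos1[inv], pos1[inv])
      flip <- reach < 2 * config$bin_width
      sgn[flip] <- -sgn[flip]
      reach[flip] <- ifelse(sgn[flip] > 0, len[flip] - 1 - pos1[inv][flip],
                            pos1[inv][flip])
      xm <- config$bin_width
      a <- config$kernel_exponent
      umax <- 1 - (xm / pmax(reach, xm + 1))^a
      u <- stats::runif(length(inv)) * umax
      d <- xm * (1 - u)^(-1 / a)
      p2 <- pmin(pmax(pos1[inv] + sgn * d, 0), len - 1)
      pos2[inv] <- floor(p2)
      b2[inv] <- bin_index(bins, chrom1[inv], pos2[inv])
    }
    base <- data.frame(chrom1 = chrom1, pos1 = pos1,
                       chrom2 = bins$chrom[b2], pos2 = pos2,
                       sample = samples, stringsAsFactors = FALSE)
  } else base <- empty

  pick_samples <- function(k) {
    k <- max(1, min(k, config$n_samples))
    sprintf("s%04d", sample.int(config$n_samples, k))
  }
  ## systematic expected breakpoint count per bin (gamma noise excluded):
  ## reference scale for fold-enrichment spikes
  mu_sys <- 2 * config$n_samples * config$rearr_per_sample *
    lambda / sum(lambda)
  truth_srb <- config$srb_spikes
  if (!is.null(truth_srb) && nrow(truth_srb)) {
    n_spiked <- integer(nrow(truth_srb))
    partner_bin <- rep(NA_integer_, nrow(truth_srb))
    extra <- do.call(rbind, lapply(seq_len(nrow(truth_srb)), function(i) {
      sp <- truth_srb[i, ]
      k <- if (!is.null(sp$fold) && !is.na(sp$fold))
        max(ceiling((sp$fold - 1) * mu_sys[sp$bin]),
            ceiling(config$spike_min_freq * config$n_samples))
      else round(sp$frequency * config$n_samples)
      who <- pick_samples(k)
      nbp <- length(who)
      n_spiked[i] <<- nbp
      partner <- if (identical(sp$regime, "clustered")) {
        partner_bin[i] <<- min(nb, sp$bin + 37)
        rep(partner_bin[i], nbp)
      } else sample.int(nb, nbp, replace = TRUE)
      data.frame(chrom1 = bins$chrom[rep(sp$bin, nbp)],
                 pos1 = rpos(rep(sp$bin, nbp)),
                 chrom2 = bins$chrom[partner], pos2 = rpos(partner),
                 sample = who, stringsAsFactors = FALSE)
    }))
    truth_srb$n_spiked <- n_spiked
    truth_srb$partner_bin <- partner_bin
    base <- rbind(base, extra)
  }
  truth_srj <- config$srj_spikes
  if (!is.null(truth_srj) && nrow(truth_srj)) {
    extra <- do.call(rbind, lapply(seq_len(nrow(truth_srj)), function(i) {
      sp <- truth_srj[i, ]
      who <- pick_samples(round(sp$frequency * config$n_samples))
      nbp <- length(who)
      data.frame(chrom1 = bins$chrom[rep(sp$bin_i, nbp)],
                 pos1 = rpos(rep(sp$bin_i, nbp)),
                 chrom2 = bins$chrom[rep(sp$bin_j, nbp)],
                 pos2 = rpos(rep(sp$bin_j, nbp)),
                 sample = who, stringsAsFactors = FALSE)
    }))
    base <- rbind(base, extra)
  }
  intra <- base$chrom1 == base$chrom2
  sv_class <- ifelse(intra,
                     sample(c("DEL", "DUP", "INV"), nrow(base),
                            replace = TRUE), "TRA")
  rearrs <- rearrangements(base$chrom1, base$pos1, base$chrom2, base$pos2,
                           base$sample, sv_class, genome = genome)
  list(rearrs = rearrs, bins = bins, genome = genome, covariates = cov,
       truth = list(srb = truth_srb, srj = truth_srj), config = config)
}

#' Simulate mutations, elements and annotations with known ground truth
#'
#' Passenger mutations are Poisson per element at the configured per-base
#' rate; driver elements additionally receive one mutation in a
#' configured fraction of patients. Signature attributions, mappability
#' and palindrome flags are drawn per mutation so the post-filters can be
#' exercised.
#'
#' @param config A [sim_config()].
#' @return List: `mutations`, `elements`, `genome`, `truth`, `config`.
#' @export
simulate_mutations <- function(config) {
  set.seed(config$seed)
  genome <- sim_genome(config)
  ## non-overlapping elements on a fixed grid
  slot <- config$element_spacing * config$element_length
  per_chrom <- floor(config$chrom_length / slot)
  stopifnot(config$n_elements <= per_chrom * config$n_chrom)
  idx <- seq_len(config$n_elements) - 1
  elements <- normalize_elements(data.frame(
    id = sprintf("e%04d", idx + 1),
    chrom = paste0("chr", idx %/% per_chrom + 1),
    start = (idx %% per_chrom) * slot,
    end = (idx %% per_chrom) * slot + config$element_length,
    element_type = "custom", stringsAsFactors = FALSE))

  mult <- if (config$mut_rate_sd > 0)
    exp(stats::rnorm(config$n_elements, 0, config$mut_rate_sd))
  else rep(1, config$n_elements)
  elements$local_rate <- log(mult)
  n_pass <- stats::rpois(config$n_elements,
    config$mut_rate * config$element_length * config$n_samples * mult)
  elem_of <- rep(seq_len(config$n_elements), n_pass)
  sample_of <- sprintf("s%04d",
                       sample.int(config$n_samples, sum(n_pass), TRUE))
  for (d in config$driver_elements) {
    k <- max(1, round(config$driver_frequency * config$n_samples))
    who <- sprintf("s%04d", sample.int(config$n_samples, k))
    elem_of <- c(elem_of, rep(d, k))
    sample_of <- c(sample_of, who)
  }
  n <- length(elem_of)
  erow <- match(sprintf("e%04d", elem_of), elements$id)
  pos <- elements$start[erow] +
    floor(stats::runif(n) * (elements$end[erow] - elements$start[erow]))
  bases <- c("A", "C", "G", "T")
  is_indel <- stats::runif(n) < config$indel_frac
  f25 <- config$indel_size_2_5_frac
  size_probs <- c(1 - f25 - 0.1, rep(f25 / 4, 4), rep(0.02, 5))
  ilen <- sample(1:10, n, replace = TRUE, prob = size_probs)
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  del <- is_indel & stats::runif(n) < 0.5
  ins <- is_indel & !del
  ref[del] <- vapply(ilen[del] + 1, function(k)
    paste(sample(bases, k, TRUE), collapse = ""), "")
  alt[del] <- substr(ref[del], 1, 1)
  alt[ins] <- vapply(ilen[ins] + 1, function(k)
    paste(sample(bases, k, TRUE), collapse = ""), "")
  ref[ins] <- substr(alt[ins], 1, 1)

  sig_names <- names(config$sig_profile)
  assigned <- sample(sig_names, n, replace = TRUE,
                     prob = config$sig_profile)
  wts <- matrix(stats::rgamma(n * length(sig_names), 0.5), nrow = n,
                ncol = length(sig_names))
  wts[cbind(seq_len(n), match(assigned, sig_names))] <-
    stats::rgamma(n, 8)
  wts <- wts / rowSums(wts)
  colnames(wts) <- paste0("sig_", sig_names)

  muts <- data.frame(chrom = elements$chrom[erow], pos = pos, ref = ref,
                     alt = alt, sample = sample_of,
                     in_mappable = stats::runif(n) < config$mappable_frac,
                     in_palindrome = stats::runif(n) < config$palindrome_frac,
                     stringsAsFactors = FALSE)
  muts <- cbind(muts, as.data.frame(wts))
  muts <- annotate_mutations(muts)
  truth <- data.frame(
    element = sprintf("e%04d", config$driver_elements),
    frequency = rep_len(config$driver_frequency,
                        length(config$driver_elements)))
  list(mutations = muts, elements = elements, genome = genome,
       truth = truth, config = config)
}

#' Simulate a per-method p-value matrix via a Gaussian copula
#'
#' Null rows are Uniform(0, 1) per method after the copula (pairwise
#' correlation `rho`), distorted per method by p -> p^gamma; planted
#' driver rows have their p values scaled down by `driver_strength`.
#'
#' @param config A [sim_config()].
#' @return List: `pmat` (a `pvalue_matrix`), `truth` (driver row keys),
#'   `config`.
#' @export
simulate_pvalue_matrix <- function(config) {
  set.seed(config$seed)
  n <- config$n_rows; k <- config$n_methods
  Sigma <- matrix(config$rho, k, k); diag(Sigma) <- 1
  Z <- matrix(stats::rnorm(n * k), n) %*% chol(Sigma)
  U <- stats::pnorm(Z)
  gamma <- rep_len(config$gamma_distortion, k)
  P <- sweep(U, 2, gamma, `^`)
  drivers <- seq_len(min(config$n_driver_rows, n))
  if (length(drivers))
    P[drivers, ] <- U[drivers, , drop = FALSE] * config$driver_strength
  if (config$missing_frac > 0) {
    drop <- matrix(stats::runif(n * k) < config$missing_frac, n)
    keepone <- cbind(seq_len(n), sample.int(k, n, TRUE))
    drop[keepone] <- FALSE
    P[drop] <- NA
  }
  cohort <- rep(c("cohortA", "cohortB"), length.out = n)
  element <- sprintf("e%04d", seq_len(n))
  long <- expand.grid(row = seq_len(n), method = seq_len(k))
  pv <- P[cbind(long$row, long$method)]
  keep <- !is.na(pv)
  pmat <- pvalue_matrix(cohort[long$row][keep], element[long$row][keep],
                        sprintf("m%02d", long$method)[keep], pv[keep])
  list(pmat = pmat,
       truth = paste(cohort[drivers], element[drivers], sep = ":"),
       config = config)
}
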