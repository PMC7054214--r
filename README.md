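# svdriverscan

Statistical toolkit for discovering somatic driver loci in cancer whole
genomes, for computational biologists working with cohort-level somatic
variant calls.

Tumour genomes accumulate thousands of passenger mutations and
rearrangements; drivers reveal themselves only as *recurrence in excess
of a realistic background*. This package implements that statistical
layer:

* **SRB scan** — significantly recurrent structural-variant breakpoints.
  Breakpoints are binned (one per sample per bin) and tested against a
  covariate-aware Gamma–Poisson background,
  log μ = β₀ + Σ βₖxₖ + log(eligible bases), variance μ + αμ², with
  BH FDR, merging of significant bins into loci, a partner-breakpoint
  **dispersion score** (normalized entropy), and classification into
  fusion-like / fragile-like / amplification / deletion / copy-neutral
  using replication timing and copy-number change.
* **SRJ scan** — significantly recurrent juxtapositions. Pairs of bins
  ("tiles" of the 2-D fusion map) are tested with a binomial tail
  against a mixture background
  p₀(i,j) ∝ w·bᵢbⱼ + (1−w)(bᵢ+bⱼ)g(dᵢⱼ) — two independent breaks
  joined, versus break-then-invasion with an empirical distance kernel —
  fitted by EM with the mixture weight profiled on a grid. Significant
  tiles carry an observed/expected **effect size** and a **robustness
  factor** (how far the background could inflate before significance is
  lost).
* **Integration** — Brown's method (moment-matched scaled χ² for
  dependent p-values) across driver-discovery methods, with per-method
  calibration QC, FDR over concatenated cohorts (Q < 0.1 significant,
  0.1 ≤ Q < 0.25 near), and the numeric post-filters (mutation/patient
  counts, mappability, palindromes, APOBEC/AID/UV signature fractions)
  with FDR recomputed after filtering.
* **Burden & excess** — negative-binomial regression burden tests over
  arbitrary element sets, a genome-wide 2-kb window scan, and excess
  (driver) mutation estimates with exact Poisson confidence intervals.
* **Power** — minimal detectable driver frequency for burden tests and
  sample-size requirements for juxtaposition detection.
* **Hotspots & indel processes** — distinct-patient hotspot tabulation
  and 2–5-bp indel enrichment / indel-rate binomial screens.
* **Simulator** — generates every input (BEDPE-like rearrangements,
  mutations, elements, covariate tracks, method p-value matrices) with
  known ground truth.

## Worked example

Simulate a 200-sample SV-dense cohort on a 60-Mb genome, plant two
recurrent-breakpoint loci at 5× their local background plus one
juxtaposition in 3% of samples, and scan:

```r
library(svdriverscan)
cfg <- sim_config(seed = 5, n_samples = 200, rearr_per_sample = 6,
                  srb_spikes = data.frame(bin = c(60, 340), fold = 5,
                                          regime = c("clustered", "dispersed")),
                  srj_spikes = data.frame(bin_i = 120, bin_j = 470,
                                          frequency = 0.03))
sim <- simulate_rearrangements(cfg)
srb <- srb_scan(sim$rearrs, sim$bins, sim$covariates,
                rep_timing = sim$covariates$timing)
srb$model
#> <srb_background> Gamma-Poisson, alpha = 0.09753
#>   coefficients:
#> (Intercept)      timing          gc
#> -10.4369283   0.6915221  -0.2645847
#>   deviance: 627.229  bins used: 600
srb$loci[, c("locus", "chrom", "start", "observed", "expected", "q",
             "dispersion", "class")]
#>     locus chrom    start observed expected       q dispersion        class
#> 1 srb_001  chr1  5900000       16     2.78 0.00181      0.481 copy-neutral
#> 2 srb_002  chr2 13900000       17     3.02 0.00181      0.885 copy-neutral
```

Both planted loci (bins 60 and 340 → starts 5.9 Mb on chr1, 13.9 Mb on
chr2) are recovered at Q < 0.1 with ~16 deduplicated breakpoints against
an expectation of ~3. The fitted overdispersion (α ≈ 0.10) and covariate
effects are estimated from the data; no copy-number track was supplied,
so the |Δ| < 0.1 band labels both loci copy-neutral. The dispersed locus
has near-maximal partner dispersion (0.885); the clustered one is pulled
to 0.481 by background breakpoints sharing its bin.

```r
srj <- srj_scan(sim$rearrs, sim$bins)
subset(srj$tiles, q < 0.1)[, c("chrom_i", "start_i", "chrom_j", "start_j",
                               "observed", "expected", "q",
                               "effect_size", "robustness_factor")]
#>   chrom_i  start_i chrom_j start_j observed expected        q effect_size robustness_factor
#> 1    chr1  5900000    chr1 9600000       10   0.0588 2.05e-14         170              4.51
#> 2    chr1 11900000    chr3 6900000        6   0.0254 3.00e-08         236              1.00
```

The planted juxtaposition (chr1 11.9 Mb ↔ chr3 6.9 Mb) is recovered with
6 samples observed against 0.025 expected (effect size 236); the
clustered SRB locus is also — correctly — a recurrent juxtaposition with
its partner bin, and would stay significant even if its background rate
were inflated 4.5-fold.

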