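---
title: "Statistical methods for somatic driver discovery from whole genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for somatic driver discovery from whole genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svdriverscan)
```

# Overview

Somatic driver discovery asks which genomic loci accumulate more
mutations or structural-variant breakpoints than a realistic background
model predicts. `svdriverscan` implements the statistical layer of that
question for whole-genome cohorts: recurrence tests for
structural-variant breakpoints (SRBs) and juxtapositions (SRJs),
integration of point-mutation driver p-values from many methods,
burden/excess estimation, discovery-power calculations, and localized
mutational-process diagnostics. A simulator generates every input with
known ground truth so the whole toolkit is testable without
controlled-access data.

All coordinates are 0-based half-open throughout (BED/BEDPE native);
1-based tables are converted explicitly, never silently.

# Recurrent breakpoints (SRB)

Breakpoints are binned into fixed-width tiles (default 100 kb,
configurable; only the juxtaposition tile size is fixed by convention,
so the SRB width is exposed as a parameter), counting **at most one
breakpoint per sample per bin** so a single rearrangement-dense tumour
cannot create a recurrence signal. The background is a Gamma–Poisson
(negative binomial) regression

$$\log \mu_i = \beta_0 + \textstyle\sum_k \beta_k x_{ik} + \log e_i,$$

where $e_i$ is the number of eligible (mappable) bases in bin $i$ — an
offset, not a covariate — and $x_{ik}$ are per-bin covariate tracks.
Covariates are pluggable; the simulator's default set is replication
timing and a GC-like track. The variance is $\mu + \alpha\mu^2$ with a
single global overdispersion $\alpha$ estimated by maximum likelihood
(`MASS::glm.nb`; data indistinguishable from Poisson fall back to a
Poisson GLM with $\alpha = 0$). Bins whose eligible bases fall below 10%
of the bin width are excluded from fitting and testing: their exposure
is too unstable for either. Constant or near-collinear covariates
(|r| > 0.999) are rejected with the offending pair named, because the
fit would otherwise silently alias them.

Per-bin significance is the upper tail $P(X \ge k_i)$ under the fitted
model, corrected by Benjamini–Hochberg; adjacent significant bins
(Q < 0.1) merge into disjoint loci whose statistics are the minimum p
and the summed observed/expected counts.

## Dispersion score and locus classes

A locus driven by a recurrent fusion has partner breakpoints that pile
into one partner bin; fragile sites and SCNA boundaries scatter their
partners genome-wide. The **rearrangement dispersion score** makes this
quantitative: partner breakpoints of all locus rearrangements are
assigned to bins and the score is the Shannon entropy of the partner-bin
frequencies divided by $\log$(number of partners), so 0 means perfectly
clustered and values near 1 mean all partners distinct. It is undefined
(reported missing) with fewer than two partners.

Classification is a fixed decision tree: dispersion ≤ 0.2 (default,
configurable) → *fusion-like*; else mean replication-timing score of
the locus > 0.5 (on a [0, 1] scale where 1 is latest-replicating) →
*fragile-like*; else the sign of the mean copy-number change across the
locus breakpoints gives *amplification* / *deletion*, with
|change| < 0.1 copies called *copy-neutral*. The fusion test precedes
the fragility split because clustered-partner loci are fusions
regardless of timing; a missing timing track yields an explicit
`unclassified-fragility` label rather than a guess. The 0.2 threshold
and the entropy formula are this package's concrete realization of the
qualitative fusion/fragile separation; only the timing cut (0.5) is a
field convention.

# Recurrent juxtapositions (SRJ)

The unit is the unordered pair of bins ("tile") holding a
rearrangement's two breakpoints, again with per-sample-per-tile
deduplication, and intra-chromosomal events shorter than 1 kb dropped as
likely artefacts (configurable). The null probability that an event
lands in tile $(i, j)$ is a two-component mixture

$$p_0(i,j) \propto w\, b_i b_j \;+\; (1-w)\,(b_i + b_j)\, g(d_{ij}),$$

the first term modelling two independent breaks joined during repair,
the second a break followed by invasion of a nearby locus. Here $b_i$ is
the raw (non-deduplicated) breakpoint rate of bin $i$ and $g$ an
empirical intra-chromosomal distance kernel on distance classes that are
lattice-resolved near the origin (bin-midpoint distances are multiples
of the width, where the kernel is steepest) and log-spaced in the tail.
Three numerical choices matter and are worth stating:

* **The kernel and the weight are estimated jointly by EM.** Each
  event's distance feeds the kernel weighted by its responsibility under
  the invasion component. A kernel pooled over all events absorbs the
  two-break component's flat intra-chromosomal floor, over-allocates
  mass to distant intra tiles, and drives the weight estimate to zero —
  the mixture becomes unidentifiable.
* **Invasion is intra-chromosomal.** Inter-chromosomal tiles carry only
  a vestigial tail mass (0.1% of the farthest distance class, keeping
  $p_0 > 0$ everywhere); inter-chromosomal events are therefore
  explained by the two-break component, which is what identifies $w$.
* **The kernel is isotonically smoothed** (non-increasing beyond the
  zero-distance class, weighted pool-adjacent-violators), encoding the
  assumption that invasion probability decreases with distance; this
  stabilizes sparse distance classes.

Each tile with at least one event is tested with a binomial upper tail
on (events in tile, total events, $p_0$); the FDR correction runs over
the full universe of tiles with nonzero exposure, zero-event tiles
entering analytically with p = 1. Significant tiles are reported with
the observed/expected **effect size** and a **robustness factor** — the
largest factor by which $p_0$ could be inflated with the tile remaining
significant at the run's raw-p threshold, found by doubling plus
bisection (relative tolerance $10^{-3}$); the tail is monotone in the
factor, so the bracket is valid.

# Integration of point-mutation driver methods

Per-element p-values from multiple upstream discovery methods are
combined with Brown's method: $X = \sum_i -2\ln p_i$ referred to a
scaled $\chi^2$ with scale $c = V/2E$ and $f = 2E^2/V$ degrees of
freedom, $E = 2k$ and $V = 4k + 2\sum_{i<j}\mathrm{cov}(-2\ln p_i,
-2\ln p_j)$. One method reduces to the identity and zero covariance to
Fisher's method. The covariance is estimated from the data by
pairwise-complete Spearman correlation mapped through
$2\sin(\pi r / 6)$ and the Kost–McDermott polynomial
$3.263r + 0.710r^2 + 0.027r^3$; a raw sample covariance of $-2\ln p$
would be dominated by the few true-signal rows, which shift all methods
jointly. Negative eigenvalues are clipped to zero. Rows with missing
methods use only their observed $k$.

Before combination, each method is calibration-checked: the inflation
factor $\lambda$ (median of $-2\ln p$ over the $\chi^2_2$ median) must
lie in [0.7, 1.5], and the Kolmogorov–Smirnov distance from uniform over
the method's own p-values above 0.1 — a null-dominated, selection-free
region, since true drivers concentrate in the lower tail — must not
exceed 0.1 (floored at the 1%-level KS critical value for small bulks).
Methods with over half their entries missing are assessed on what is
present and flagged low-coverage.

The FDR is controlled by concatenating combined p-values across all
tumour-type cohorts and applying Benjamini–Hochberg once; Q < 0.1 is
significant and 0.1 ≤ Q < 0.25 "near significance". Candidates then pass
numeric post-filters — at least 3 mutations in at least 3 patients, more
than 50% of mutations mappable, under 50% in palindromic DNA, under 50%
attributed to APOBEC, plus cohort-specific cuts (AID < 35% in lymphoid,
UV < 50% in melanoma; attribution is the per-mutation
maximum-likelihood signature supplied as input) — and the FDR is
recomputed over the survivors. Filters whose annotation is absent are
reported not-evaluable and flag the candidate rather than failing it.
Palindrome and mappability annotations are consumed as input; the
simulator draws them as Bernoulli flags, since the toolkit deliberately
has no reference-sequence dependence.

# Burden, excess, power, and local processes

**Burden (NBR).** Per-element counts are modelled by a log-link negative
binomial regression on covariates (e.g. local mutation rate, expression,
copy number) with log-length offset, fitted on putative passenger
elements; candidate elements are tested against their predicted
expectation with the NB upper tail. A genome-wide 2-kb window scan uses
the same machinery with BH within the scanned set. The full
trinucleotide-context substitution model of upstream burden callers is
deliberately not reproduced — rate heterogeneity enters only through
covariates and the dispersion — and this is a stated fidelity limit.

**Excess.** The excess (driver) mutation estimate for an element set is
observed − expected, with a 95% interval from the exact Poisson interval
on the observed count, the expectation treated as fixed; the lower bound
can therefore never fall below −expected.

**Power.** The minimal driver frequency detectable at ≥ 90% power solves
a binomial burden design: per-patient background probability
$q_0 = 1 - (1 - r)^L$, critical count $k^*$ at the per-test level
$\alpha_{\mathrm{global}}/n_{\mathrm{tests}}$ (default global rate 0.1),
and driver-plus-background mixing $q_0 + f s (1 - q_0)$ — the union of
independent events, not simple addition — solved for $f$ by bisection to
$10^{-5}$. The juxtaposition analogue spreads the per-sample
rearrangement count over the 2-D tile map. One discreteness artifact is
worth knowing: $k^*$ is a step function of the background rate, and
while it is pinned, a slightly larger background *helps* reach it, so
$f^*$ can decrease by up to $\Delta q_0 / s$ between steps; across
rate differences large enough to move $k^*$, the grid is monotone.

**Hotspots and indels.** Hotspot tabulation counts distinct patients per
SNV position (ties broken by genome order). The 2–5-bp indel screen
compares each gene's proportion of 2–5-bp indels (inclusive bounds,
length = |len(ref) − len(alt)|) to the cohort background by a one-sided
binomial test, the background computed from all *other* genes' indels
(self excluded, so a strong gene cannot dilute its own test); the rate
test compares total indel counts to a length-share expectation. The two
families are FDR-corrected separately.

# The simulator and what passing tests mean

`simulate_rearrangements()` inverts the SRB/SRJ generative assumptions:
per-bin intensity from the covariate log-linear model times a gamma
multiplier (overdispersion), per-sample Poisson event counts, partners
drawn from the two-component mixture with a truncated-Pareto invasion
kernel, and planted SRB loci (specified as fold-enrichment over the
bin's own systematic background, floored at 3% of the cohort) and SRJ
pairs recorded in a truth table. `simulate_mutations()` places Poisson
passenger mutations in elements (optional log-normal local-rate
heterogeneity, returned as a covariate), spikes driver elements in a
configured fraction of patients, and draws signature, mappability and
palindrome annotations. `simulate_pvalue_matrix()` is a Gaussian copula
with per-method distortion $p \to p^\gamma$ and multiplicatively
sharpened driver rows. One config object with a mandatory seed drives
everything; identical seeds give bit-identical output.

Default study conditions were chosen once, from typical whole-genome
cohort scales, and are not tuned per test: spike-in experiments use a
200-sample SV-dense cohort (≈ 6 rearrangements per sample on the
simulated 60-Mb region, i.e. ≈ 300 genome-wide — breast/ovarian-like);
calibration experiments use pan-cancer densities (≈ 25 breakpoints per
100-kb bin over 10,000 bins; ≈ 22 events per tile over 11,325 tiles;
≈ 25 SNVs per 2-kb window over 10,000 windows). The densities matter
because the unit-level tests are discrete: at sparse counts the
attainable level of "p < 0.01" sits well below 0.01 and a calibration
check is uninformative.

Calibration is asserted on nulls drawn *from each fitted background*
(parametric bootstrap), which is the property the tests themselves
guarantee. The fully closed loop — generate from the simulator, refit,
test — is also calibrated for the SRB and burden models; for the SRJ
model it is residually inflated (≈ 2–3% of tiles below p = 0.01 at 22
events per tile) because the marginal density of invasion *partner* ends
is a smoothed version of the per-bin break rate, not the rate itself.
At realistic sparse tile occupancies this residual is immaterial — the
spike-in experiments bound the realized false-discovery proportion
directly — but dense-map users should know the background is an
approximation. The simulator also does not emulate complex multi-break
events, per-sample covariate interactions, or sequence-level features of
real genomes, so passing tests demonstrate statistical correctness of
the methods, not fidelity to any particular tumour cohort.

# Known limitations

* The SRJ background's functional form is one concrete realization of
  break rates + distance + repair-mechanism mixing; the upstream
  contract it honours is qualitative (monotone in rates, decreasing in
  distance, normalized).
* Copy-number change per locus is consumed as input; no segmentation is
  performed. Gene annotation of loci is left to downstream joins.
* Brown's combination assumes the per-method dependence is adequately
  summarized by rank correlations; heavy tail co-movement beyond that is
  not modelled.
* Exact binomial/NB tails are conservative for discrete counts; no
  mid-p option is provided.
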