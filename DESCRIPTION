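Package: svdriverscan
Title: Driver-Discovery Statistics for Somatic Structural Variants and
    Point Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for discovering somatic driver loci in
    cancer whole genomes. Detects significantly recurrent structural-variant
    breakpoints (SRBs) under a covariate-aware Gamma-Poisson background with
    dispersion-based fusion/fragile-site classification, and significantly
    recurrent juxtapositions (SRJs) between pairs of loci under a
    break-rate and distance-aware binomial background with effect sizes and
    robustness factors. Combines per-element p-values from multiple
    point-mutation driver-discovery methods with Brown's method, controls
    the false discovery rate across cohorts, and applies signature- and
    artefact-based post-filters. Also provides burden testing and excess
    (driver) mutation estimation via negative-binomial regression,
    discovery-power calculations, hotspot tabulation, 2-5-bp indel
    enrichment tests, and a simulator generating all inputs with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
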