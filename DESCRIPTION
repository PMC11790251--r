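Package: gapcnv
Title: Simulation-Based Inference of GAP1 Copy-Number Variant Adaptation Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evolutionary modelling and amortized simulation-based inference for
    adaptive copy-number amplification of the yeast GAP1 locus in glutamine-limited
    chemostats. Provides a four-genotype Wright-Fisher simulator with a
    reporter-failure genotype, summary statistics for CNV dynamics (appearance,
    per-generation increase, equilibrium), a Gaussian-mixture conditional density
    estimator for the CNV formation rate, selection coefficient and pre-existing
    unreported-CNV proportion, collective (replicate-aggregated) posteriors on a
    Riemann grid, and model-based predictions: posterior-predictive trajectories,
    lineage-tracked Shannon diversity, and two-strain competition simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
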