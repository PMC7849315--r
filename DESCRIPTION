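Package: nitroroot
Title: Multicellular Modelling of Nitrogen-Source-Dependent Root Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled per-cell ordinary differential equations for auxin,
    PIN2 trafficking and polarity, a division factor and cell growth in the
    epidermis and cortex files of the Arabidopsis root tip, under ammonium
    or nitrate nutrition. Provides a deterministic multicellular simulator
    with division, elongation-transition and window-advection events and a
    closed auxin mass ledger; Bayesian calibration of the model against
    tidy observation tables with an adaptive Metropolis sampler; model
    comparison of alternative auxin-source scenarios by Pareto-smoothed
    importance-sampling leave-one-out cross-validation (PSIS-LOO); and a
    seeded synthetic-data generator that emulates cell-length,
    PIN2-membrane-intensity and ratiometric auxin-reporter measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
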