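Package: bayesvas
Title: Bayesian Analysis of Censored Visual-Analog-Scale Rating Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prospective two-group pre/post studies that measure
    bounded 0-100 visual-analog-scale (VAS) ratings and region-of-interest
    fMRI time courses. Implements hierarchical Bayesian censored (Tobit)
    regression for rating data with per-subject residual variances,
    Savage-Dickey and sign-restricted Bayes-factor hypothesis tests,
    default one-sided JZS t-test Bayes factors, test-retest reliability
    from random-effect variance components, Bayes-factor design analysis
    by Monte-Carlo simulation, noncentral-F power for the within-between
    ANOVA interaction, and a simplified hierarchical model for
    HRF-convolved ROI signal time courses. Synthetic-data generators
    emulate every input so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    coda,
    rjags,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
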