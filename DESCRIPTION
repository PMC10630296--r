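Package: dlgrowth
Title: Double-Logistic Growth Modeling and Cross-Sectional Resampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian multilevel modeling of longitudinal growth in linear
    skeletal traits with a double-logistic growth equation, and a resampling
    framework for quantifying how well repeated cross-sectional subsamples
    (one observation per individual) recover longitudinal growth standards
    and milestones such as peak growth velocity (PGV) and age at peak growth
    velocity (aPGV). Includes a synthetic longitudinal data generator,
    genetic-algorithm prior elicitation with prior predictive checks,
    MCMC (via JAGS) and maximum a posteriori fitting, posterior predictive
    growth-percentile intervals, and agreement metrics (mean absolute
    difference curves, milestone errors, growth-rate RMSD).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rjags,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
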