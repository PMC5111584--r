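Package: synthregion
Title: Synthetic Control Estimation for Policies with Multiple Treated Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates average treatment effects on the treated for policies
    that affect many units at once (for example, all hospitals in one region)
    by aggregating the treated units into a single treated region and building
    a synthetic control region as a convex, patient-frequency-weighted
    combination of donor units. Implements the nested choice of predictor
    importance weights (V) and donor weights (W) that minimises pre-treatment
    prediction error, region-resampling placebo tests for inference, and the
    standard comparators: two-way fixed-effects difference-in-differences with
    cluster-robust errors, Mahalanobis matching plus DiD, per-unit synthetic
    controls with frequency-weighted aggregation, a synthetic-control-plus-DiD
    hybrid, and leave-one-region-out sensitivity analysis. Ships a factor-model
    panel generator (common time effects, time-varying loadings on unobserved
    unit factors, covariate effects, transitory noise) and a patient-level
    logistic risk-adjustment stage producing risk-adjusted mortality in
    percentage points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    ggplot2,
    jsonlite,
    rlang,
    sandwich,
    stats,
    utils,
    withr,
    yaml
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
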