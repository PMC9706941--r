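Package: failtiming
Title: Failure-Timing Analysis for Locoregionally Advanced Nasopharyngeal
    Carcinoma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Survival-analysis pipeline for studying the timing of treatment
    failure in locoregionally advanced nasopharyngeal carcinoma (LANPC)
    cohorts treated with induction chemotherapy followed by radiotherapy with
    or without concurrent cisplatin.  Derives the study endpoints (overall,
    failure-free, locoregional- and distant-failure-free survival, and
    post-failure overall survival) from a per-patient table; finds the
    optimal early-versus-late failure cut-off by a minimum-P-value log-rank
    scan over candidate thresholds with a resampling correction for the
    multiplicity of the scan; fits multivariable Cox proportional-hazards
    models with univariable screening and backward elimination; and estimates
    covariate-adjusted cumulative and monthly time-specific failure
    probabilities per concurrent-chemotherapy dose group with a random
    survival forest (log-rank splits, Nelson-Aalen terminal-node estimates).
    A calibrated synthetic-cohort generator with a configurable failure-time
    change-point stands in for restricted clinical data and doubles as the
    ground truth for the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
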