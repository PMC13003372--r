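Package: ewsbench
Title: Validation Toolkit for Early Warning Scores in Older Emergency
    Department Patients
Version: 0.1.0
Authors@R:
    person("ewsbench", "maintainers", email = "ewsbench@example.org",
           role = c("aut", "cre"))
Description: Computes five early warning scores (NEWS, NEWS2, MEWS, REMS,
    IEWS) from emergency-department vital signs via a generic, validated
    band-table engine, and benchmarks their 24-hour deterioration prediction
    in patients aged 80 years or older: discrimination (AUROC with DeLong
    comparisons, sliding 5-year age windows with restricted-cubic-spline
    trends), calibration (Brier scores with bootstrap inference, logistic
    calibration slopes), classification at positive-predictive-value margins,
    precision-recall analysis, and gradient-boosted-tree Shapley
    contribution contrasts between age strata. Includes a synthetic cohort
    generator emulating the class-conditional vitals structure of a large
    geriatric ED population, multiple-imputation handling of sparse missing
    vitals, and a reproducible end-to-end pipeline with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
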