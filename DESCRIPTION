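Package: gksurv
Title: Local Control Survival Modelling and Dose Decision Support for
    Gamma Knife Radiosurgery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lesion-level modelling of time to local failure after Gamma
    Knife radiosurgery for recurrent glioblastoma. Provides a random
    survival forest with log-rank splitting and Nelson-Aalen leaf
    estimators, leakage-resistant patient-level grouped cross-validation
    with censoring-adjusted Brier scores and Harrell's concordance index,
    permutation importance, cluster-bootstrap confidence intervals, a
    counterfactual prescription-dose sweep engine that recommends a dose
    and returns individualized local-control predictions, and a synthetic
    cohort generator with a known Weibull proportional-hazards
    dose-response for end-to-end testing without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    survival,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    ranger
Config/testthat/edition: 3
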