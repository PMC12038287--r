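Package: qtcds
Title: Evaluation Pipeline for QT-Prolongation Clinical Decision Support Alerts
Version: 0.1.0
Authors@R: person("QTCDS", "Maintainers", email = "maintainers@qtcds.org", role = c("aut", "cre"))
Description: End-to-end, testable pipeline for evaluating an interruptive,
    alert-based clinical decision support (CDS) tool for drug-induced long-QT
    syndrome (diLQTS). Provides heart-rate-corrected QT computation (Bazett and
    a QRS-adjusted Fridericia variant), the alert firing rule and provider
    compliance classification, outcome adjudication, comorbidity clustering by
    K-means with Hamming distance on one-hot diagnosis and medication codes,
    descriptive cohort summaries with population-standardized measures, and
    marginal logistic and Poisson regression via generalized estimating
    equations with exchangeable within-patient correlation and robust standard
    errors. A fully synthetic electronic health record generator with a
    ground-truth registry makes every stage testable without access to
    restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
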