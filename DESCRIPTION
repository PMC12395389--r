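Package: strokeRK
Title: Validation of Rule-Based and Rothman-Keller Stroke Risk Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating three-level stroke risk
    stratification schemes in community screening cohorts. Implements the
    Chinese "8+2" rule-based risk classifier, a logistic risk model fitted by
    iteratively reweighted least squares, and the Rothman-Keller risk-synthesis
    model (per-factor baseline morbidity ratios, exposure risk scores, the
    combined multiplicative-additive score, and individual relative risk).
    Risk-category cut points are derived by a binomial Monte-Carlo simulation
    of exposure profiles, and competing models are compared with ROC/AUC,
    paired DeLong tests, sensitivity/specificity, and three-category net
    reclassification improvement. A synthetic cohort generator with known
    logistic truth makes every pipeline stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pROC,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
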