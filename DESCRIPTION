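Package: trisk
Title: Transformer and ODE-Based Survival Modelling for Longitudinal Coded EHR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Risk prediction for heart-failure cohorts from longitudinal coded
    electronic health records. Implements a transformer sequence encoder over
    diagnosis, medication and procedure codes with age and visit-position
    channels, an ordinary-differential-equation survival head trained by
    censored maximum likelihood with an explicit D-calibration (XCal)
    regulariser, transfer learning across vocabularies, a MAGGIC-EHR-style Cox
    benchmark with chained-equation multiple imputation and Rubin's-rules
    pooling, a censoring-aware evaluation suite (concordance, AUPRC,
    calibration curves and ICI, D-calibration, decision curves, impact
    analysis, subgroup analysis), integrated-gradients explainability, and a
    synthetic-cohort generator with known hazard structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    nnet,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
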