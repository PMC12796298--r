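Package: tmsmep
Title: Cortical Excitability Metrics and Diagnostic Classification from TMS
    Motor-Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the ratio-to-baseline cortical excitability metrics delta
    (MEP amplitude relative to the harmonic mean of a within-session
    single-pulse baseline) and rho (relative to the arithmetic mean) from
    transcranial magnetic stimulation (TMS) motor-evoked potential (MEP)
    amplitude tables, and runs a complete diagnostic-biomarker evaluation
    around them: IQR-based outlier removal, Gamma maximum-likelihood fits with
    Kolmogorov-Smirnov goodness-of-fit tests per ISI-by-group cell, a principal
    component mixed-effects logistic model of diagnostic status, and a
    three-feature-set gradient-boosting comparison with SHAP and Gini
    attribution under stratified cross-validation. Includes a seeded synthetic
    cohort generator emulating a paired-pulse facilitation/inhibition protocol
    so the full pipeline is reproducible without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    lme4,
    xgboost,
    fitdistrplus,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
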