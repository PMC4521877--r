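Package: cardiotwin
Title: Desk-Scale Multi-Scale Heart-Failure Simulator with Model Personalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds synthetic bi-ventricular anatomies with rule-based fiber
    architecture, solves monodomain Mitchell-Schaeffer electrophysiology with
    fast sub-endocardial conduction layers, synthesizes 12-lead
    pseudo-electrocardiograms, couples co-rotational finite-element
    biomechanics to three-element Windkessel hemodynamics with four-phase
    valve logic, and personalizes the electrical, hemodynamic and mechanical
    parameters against clinical-style targets (QRS duration, electrical axis,
    QT interval, ejection fraction, stroke volume, ventricular volumes and
    pressures). Includes cardiac resynchronization pacing protocols, a
    virtual-cohort generator with configurable covariate correlations, and a
    small statistics pipeline (Pearson correlation with significance, Grubbs
    single-outlier test, cohort summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
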