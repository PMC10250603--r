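Package: pzapk
Title: Population Pharmacokinetics of Pyrazinamide with Geriatric-Diabetes
    Covariate Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Nonlinear mixed-effects modelling of steady-state pyrazinamide
    plasma concentrations in tuberculosis patients. Implements a
    one-compartment oral-absorption model with allometric scaling on lean
    body weight and a geriatric diabetes-mellitus covariate on apparent
    clearance, estimated by first-order conditional estimation with
    interaction (FOCE-I). Includes likelihood-ratio covariate selection,
    below-quantification-limit imputation, empirical Bayes (MAP) individual
    estimation and exposure forecasting, prediction-corrected visual
    predictive checks, nonparametric bootstrap, external-validation error
    metrics, and a synthetic-cohort generator emulating a sparse
    therapeutic-drug-monitoring design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
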