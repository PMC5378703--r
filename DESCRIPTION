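Package: eqmisfit
Title: Consequences of IRT Model Misfit in Mixed-Format Test Equating
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation pipeline for studying the practical consequences of
    item response theory (IRT) model misfit on test equating and performance
    classification with mixed-format test data. Generates NEAT-design
    (common-item nonequivalent groups) response data under a 3PL/2PL/GPC
    truth, calibrates item parameters by marginal maximum likelihood EM under
    nested well-fitting and misfitting model sets, links scales by mean/sigma,
    Stocking-Lord, or fixed common item parameter (FCIP) calibration, equates
    number-correct scores by IRT true-score equating, and quantifies
    consequences through equating-error statistics (MEE, RMSEE, REMSEE) and
    classification/passing-rate misclassification against the known truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
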