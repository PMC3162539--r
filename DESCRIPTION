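Package: bayesdisc
Title: Bayesian Optimal Discretization of Continuous Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised discretization of continuous predictors against a
    categorical target. Implements a Bayesian score over discretizations
    (a Poisson-process structure prior over cut-point placement combined
    with a Dirichlet-multinomial marginal likelihood per interval) that is
    optimized exactly by dynamic programming, alongside the classical
    Fayyad-Irani recursive entropy-minimization method with the MDLPC
    stopping rule. Includes a discrete naive Bayes classifier, a stratified
    repeated cross-validation harness with accuracy, multi-class AUC
    (Hand-Till), robustness, selection-stability and interval-complexity
    measures, seeded synthetic-data generators with known cut-point
    structure, and JSON model serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
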