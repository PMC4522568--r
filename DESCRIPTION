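Package: mtmmsim
Title: Monte Carlo Study of Multitrait-Multimethod Confirmatory Factor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the behaviour of single-trait multimethod
    confirmatory factor models under matched and mismatched measurement
    designs. Defines four competing model structures for a design with three
    methods and three indicators per method (constrained and unconstrained
    uncorrelated-methods models, the correlated methods-minus-one model, and
    the fully correlated-methods model), synthesises population covariance
    matrices from stated consistency and reliability levels, fits the models
    by normal-theory maximum likelihood with equality constraints and
    unbounded parameters, and aggregates convergence failures, improper
    solutions (non-positive-definite error or latent covariance matrices),
    fit-index rejection rates (chi-square, RMSEA, CFI, SRMR), and
    method-factor collapse across a full simulation design grid.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
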