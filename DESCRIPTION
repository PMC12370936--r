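Package: dualpath
Title: Dual Adaptation Pathways in Relational Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses how learning systems with separate
    representational and relational modules resolve violations of relational
    expectations. Provides a procedural generator for an order-discrimination
    task (shapes on a 3x3 grid with one predictive feature), a convolutional
    dual-module agent trained by stochastic gradient descent on a
    ring-regularized loss, rule-reversal and intermediate-step training
    protocols with adaptation-pathway classification and logistic estimation
    of the inflection point, and a reduced scalar model with gradient-flow
    integration, fixed-point and stability analysis, closed-form
    weak-regularization solutions, and pathway-boundary maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
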