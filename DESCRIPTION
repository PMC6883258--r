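Package: hdma
Title: High-Dimensional Mediation Analysis with De-Sparsified Lasso Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests mediation effects of high-dimensional, correlated mediators
    (such as DNA methylation M-values) between an exposure and a binary or
    continuous outcome. Implements a three-stage procedure: sure independence
    screening to reduce the mediator dimension to n/log(n), de-sparsified
    (de-biased) lasso inference on the joint outcome model for per-mediator
    p-values in the p >= n regime, and an intersection-union (joint
    significance) test combining the exposure-to-mediator and
    mediator-to-outcome paths. Includes the scaled-lasso noise estimator, a
    minimax-concave-penalty (MCP) selection-plus-refit comparator, a synthetic
    data generator with AR(1)-correlated mediators, and a Monte-Carlo harness
    for power and type-I-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    stats,
    utils,
    jsonlite,
    data.table,
    parallel,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
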