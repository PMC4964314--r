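Package: bepr
Title: Bootstrap-Enhanced Penalized Regression for Correlated Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Variable selection for regression problems with many highly
    correlated predictors, as arise when relating intrinsic connectivity
    network (ICN) coherence metrics to individual-difference criteria. Fits
    ordinary least squares, ridge, elastic-net and lasso models by cyclic
    coordinate descent with cross-validated penalty tuning, resamples subjects
    with a nonparametric bootstrap, and converts the bootstrap coefficient
    distributions into two selection rules: the variable inclusion probability
    (VIP, the fraction of replicates with a nonzero coefficient) and the
    bootstrap quantile rule (QNT, a percentile confidence interval that must
    exclude zero). Includes a bias-corrected post-selection refit, a generator
    for correlated synthetic designs, and a Monte Carlo harness that measures
    Type I error and power of each rule across sample sizes and noise levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
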