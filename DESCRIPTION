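Package: bivalvepop
Title: Distribution and Abundance Modelling for Epifaunal Bivalve
    Population Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A hurdle-style workflow for estimating coastal population
    sizes of epifaunal bivalves (mussels and oysters) from stratified
    survey data and gridded environmental covariates.  Combines
    collinearity screening of predictors, zero-one-inflated models of
    proportional substrate cover, boosted-tree presence-absence models
    with prevalence-matched classification thresholds, conditional
    abundance models on the log scale with regression-of-observed-on-
    estimated recalibration and Duan's smearing retransformation, and
    three population-size estimators with propagated standard errors.
    All model performance is assessed with the bootstrap 0.632+
    estimator.  A synthetic seascape generator with known truth makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
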