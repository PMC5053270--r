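Package: costreg
Title: Regression Methods for Heavy-Tailed Healthcare Cost Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits and compares sixteen regression estimators for strictly
    positive, right-skewed and leptokurtic outcomes such as annual hospital
    costs: linear regression on levels and on log- or square-root-transformed
    costs with covariate-dependent Duan smearing retransformation,
    quasi-likelihood generalized linear models with log or square-root links
    and Poisson- or gamma-type variance, maximum-likelihood lognormal,
    generalized gamma and generalized beta of the second kind regressions,
    two-component finite mixtures of gamma densities, extended estimating
    equations with a Box-Cox link and power variance, and conditional density
    approximation estimators built from interval-membership logit models.
    Includes a synthetic cost-data generator with known data-generating
    processes, forecast-evaluation metrics (MPE, MAPE, RMSE, ADMPE, Pearson
    misspecification test, decile profiles, response surfaces against inverse
    sample size), and a quasi-Monte-Carlo harness that repeatedly estimates
    models on samples from an estimation subpopulation and scores mean-cost
    forecasts on a held-out validation subpopulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    withr,
    yaml
Config/testthat/edition: 3
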