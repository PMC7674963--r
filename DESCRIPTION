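Package: milkRRM
Title: Random Regression Test-Day Models for Milk Yield
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fits random regression test-day models for daily milk yield in
    dairy cattle. Genetic and permanent-environment effects are modelled as
    random regressions on normalized Legendre polynomials of days in milk
    (orders one to five), with herd-year-season, calving-age and days-in-milk
    fixed effects. Variance components are estimated by restricted maximum
    likelihood (average-information REML with expectation-maximisation
    safeguards) on Henderson's mixed-model equations, using the sparse inverse
    numerator relationship matrix built from pedigree with inbreeding.
    Residual variance can be homogeneous or heterogeneous across ten
    days-in-milk classes via iterative variance weighting. The package
    computes daily and 305-day breeding values, heritability and repeatability
    trajectories, AIC/BIC model comparison, predictive validation through
    full/reduced data splits, and includes a synthetic herd generator with
    the same covariance-function structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    yaml,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
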