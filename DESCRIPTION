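Package: steppeRK
Title: Regression Kriging of Grassland Carbon Stocks from Multispectral Reflectance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to scale plot-measured grassland above-ground carbon
    stocks to regional maps using regression kriging on multiband surface
    reflectance covariates. Includes vegetation-index computation
    (NDVI, WDRVI, CI, EVI, SR) and biomass-to-carbon conversion, empirical
    semivariogram estimation with exponential, Gaussian and spherical model
    fitting, an ordinary-kriging solver for regression residuals,
    leave-one-out cross-validation of regression-kriging against a linear
    regression baseline, stratified per-steppe modelling with mosaicking,
    zonal carbon accounting, and a seeded synthetic-field generator with
    known trend and residual variogram structure for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
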