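Package: fluxgpr
Title: Tower-to-Grid Upscaling of Terrestrial Carbon Fluxes with Gaussian
    Process Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gaussian process regression with an automatic-relevance-
    determination squared-exponential kernel for estimating terrestrial
    carbon fluxes (gross primary productivity, ecosystem respiration, net
    ecosystem exchange) from eddy-covariance tower predictor tables, and
    for upscaling the fitted models onto gridded leaf-area-index and
    climate predictor stacks with per-pixel epistemic uncertainty.
    Includes a synthetic data generator emulating tower tables, tower time
    series and two-resolution raster scenes; k-fold cross-validation with
    R2, RMSE and normalized RMSE; 8-day compositing, bilinear resampling
    and annual aggregation to gC m-2 y-1; ARD predictor-relevance ranking
    and temporal driver correlations; and gridded product intercomparison
    (per-pixel correlation and RMSE maps, NEE consistency).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
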