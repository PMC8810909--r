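Package: urbancline
Title: Urban-Rural Clines in Melanism from Crowdsourced Occurrence Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating urban-rural clines in a binary color
    phenotype from crowdsourced occurrence records. Aggregates
    per-image classification votes into observations, builds buffered
    city study regions, spatially thins records, extracts raster
    covariates with exact cell-intersection weights, fits a binomial
    random-intercept mixed model (Laplace approximation) with
    urbanization interactions, corrects residual spatial
    autocorrelation with a residual autocovariate, and runs Moran's I
    correlogram diagnostics and thinning/buffer sensitivity analyses.
    Includes a synthetic-data generator that reproduces the assumed
    generative model so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
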