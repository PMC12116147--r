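Package: pmFusion
Title: Satellite-Based Estimation of Surface PM2.5 with Spatiotemporal Gap
    Filling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates hourly surface PM2.5 concentrations from geostationary
    satellite observations. Provides a spatiotemporal convolutional imputer
    that fills cloud-induced gaps in top-of-atmosphere reflectance (TOAR) and
    aerosol optical depth (AOD) cubes, fuses the gap-filled fields with
    meteorological reanalysis and ground-station measurements into hourly
    training tables, fits four cross-validated regression learners (random
    forest, two gradient-boosting variants, support vector regression), and
    summarizes population-weighted exposure against air-quality standards.
    A seeded synthetic-scene generator with known ground truth makes every
    stage testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ranger,
    xgboost,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Regression, Spatial, Epidemiology
RoxygenNote: 7.3.3
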