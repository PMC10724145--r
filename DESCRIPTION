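Package: oxymap
Title: Surface Oxygen Concentration Estimation and Mapping for High-Elevation Terrain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating and mapping near-surface oxygen
    concentration over high-elevation terrain from elevation, air
    temperature and leaf area index. Implements a contribution-weighted
    composite index built from Min-Max normalized predictors, a linear
    oxygen-concentration model fitted by repeated random-subsampling
    cross-validation with RMSE-stability model selection, pairwise linear
    harmonization of multi-instrument field measurements, grid-by-grid
    application of the fitted model to co-registered raster stacks with an
    ensemble standard-deviation uncertainty layer, stratified one-sample
    t-test validation of field data, and a seeded synthetic-data generator
    for points, calibration sessions and raster stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'measurements-io.R'
    'calibration.R'
    'estimation.R'
    'raster-io.R'
    'mapping.R'
    'validation.R'
    'synthetic.R'
    'oxymap-package.R'
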