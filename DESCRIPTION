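Package: chlorospec
Title: Multi-Temporal Retrieval of SPAD-Based Leaf Chlorophyll from
    Hyperspectral Reflectance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A machine-learning workflow for retrieving leaf chlorophyll
    (as SPAD meter units) from 400-1000 nm hyperspectral reflectance across
    multiple field campaigns. Provides a synthetic field-trial generator
    (campaign SPAD distributions, Beer-Lambert leaf spectra, mini
    reflectance data-cubes with calibration panels), ENVI-style cube and
    sample-table input/output, a spectral preprocessing chain (Gaussian
    spectral-response resampling, per-band empirical-line calibration,
    Savitzky-Golay smoothing, minimum-noise-fraction denoising), a
    sixty-index pigment vegetation-index registry with derivative and
    continuum-removal operators, a seventeen-model regression harness with
    sequential and cumulative-retraining learning strategies and
    accuracy-threshold model selection, cross-model feature-importance
    consensus (PLSR weights, random-forest importance, Gaussian-process ARD
    length scales), and pixel- and plant-level SPAD prediction maps with
    uncertainty layers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    rpart,
    randomForest,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab,
    mixOmics,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'chlorospec-package.R'
    'utils.R'
    'io-samples.R'
    'sensor.R'
    'preprocess.R'
    'indices-ops.R'
    'indices-registry.R'
    'dataset.R'
    'metrics.R'
    'gp.R'
    'plsr.R'
    'models.R'
    'importance.R'
    'strategies.R'
    'experiments.R'
    'io-envi.R'
    'mapping.R'
    'synth.R'
    'pipeline.R'
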