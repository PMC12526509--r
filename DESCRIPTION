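Package: texSMC
Title: Soil Moisture Estimation from UAV Multispectral Canopy Texture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates volumetric soil moisture content (SMC) at three soil
    depths (0-20, 20-40, 40-60 cm) from six-band UAV multispectral canopy
    imagery. Implements windowed gray-level co-occurrence matrix (GLCM)
    texture features (mean, variance, homogeneity, contrast, dissimilarity,
    entropy, second moment, correlation) over the 48 metric-by-band
    "positions", two- and three-dimensional texture indices built from
    position tuples, exhaustive correlation-matrix feature screening with
    significance, redundancy (|r| >= 0.90) and variance-inflation filters,
    and depth-resolved regression with random forest, partial least squares
    and a single-hidden-layer tanh neural network over seven feature-fusion
    input combinations. A synthetic Gaussian-random-field canopy generator
    with controllable texture-moisture coupling supports end-to-end testing
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    pracma,
    randomForest,
    mixOmics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'evaluation.R'
    'glcm.R'
    'indices.R'
    'modeling.R'
    'raster.R'
    'screening.R'
    'synthetic.R'
    'utils.R'
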