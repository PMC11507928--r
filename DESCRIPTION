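Package: hsigrade
Title: Hyperspectral Grade Classification of Edible Oils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Pipeline for grade classification of edible oils (camellia seed
    oil in particular) from near-infrared hyperspectral image cubes. Covers
    ENVI cube input/output, region-of-interest mean-spectrum extraction,
    Euclidean-distance outlier screening, Kennard-Stone calibration/prediction
    splitting, spectral preprocessing (Savitzky-Golay smoothing and
    derivatives, min-max normalization, standard normal variate),
    characteristic-wavelength selection by the successive projections
    algorithm (SPA) and competitive adaptive reweighted sampling (CARS) over a
    cross-validated PLS core, gray-level co-occurrence matrix (GLCM) texture
    features at characteristic wavelengths with per-sample image PCA, and
    genetic-algorithm-tuned RBF support vector machine grading models with
    model-comparison arithmetic. A synthetic cube generator with known
    ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    EBImage,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
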