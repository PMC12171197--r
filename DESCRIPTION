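Package: hyperleaf
Title: Leaf Water Content Estimation from Near-Infrared Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating gravimetric leaf water content from
    near-infrared (900-1700 nm) hyperspectral reflectance. Implements
    black/white reflectance calibration and ENVI cube I/O, leaf/background
    segmentation, spectral preprocessing (SNV, MSC, Savitzky-Golay,
    derivatives, normalization), the Near-Infrared Slope Difference Index
    (NISDI) together with exhaustive two-band DVI/RVI/NDVI searches,
    characteristic-wavelength selection by CARS, SPA and UVE, chemometric
    regression back-ends (PLSR, MLR, random forest, feed-forward network),
    per-pixel water-content mapping, and an end-to-end study pipeline with a
    synthetic-data generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    randomForest,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    signal
Config/testthat/edition: 3
RoxygenNote: 7.3.3
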