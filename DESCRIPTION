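Package: hsiphen
Title: Hyperspectral Growth-Monitoring Toolkit for Plant Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating leaf chlorophyll status (SPAD) and
    aboveground biomass from hyperspectral imagery of cultivated plants.
    Reads ENVI-style reflectance cubes and tabular spectra, applies
    chemometric pretreatments (SNV, MSC, Savitzky-Golay smoothing, first
    derivative), selects informative wavelengths with competitive adaptive
    reweighted sampling (CARS) and a dynamic reptile search algorithm
    coupled to CARS (DRSA-CARS), extracts red-edge-optimized vegetation
    indices and PCA-guided GLCM texture features, fuses feature sets, and
    fits and evaluates PLSR, SVR, feed-forward and 1-D convolutional
    network regression models. A seeded synthetic-data module generates
    leaf-like spectra and textured plant cubes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    ggplot2,
    generics,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
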