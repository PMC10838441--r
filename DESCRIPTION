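Package: chlorospec
Title: Chlorophyll Estimation from Vis-NIR Hyperspectral Images of Leafy Vegetables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for estimating leaf total chlorophyll (SPAD
    units) from visible/near-infrared hyperspectral images of leafy vegetables
    such as lettuce. Provides radiometric reflectance calibration against white
    and dark reference frames, ENVI-format cube input/output, Otsu-plus-
    morphology foreground segmentation, region-of-interest mean-spectrum
    extraction, chemometric preprocessing (min-max scaling, first-derivative
    spectra, offset/slope augmentation), a one-dimensional convolutional
    regression network with a squeeze-and-excitation spectral attention gate
    and an Inception-style multi-scale block trained by Adam with cosine
    learning-rate annealing, classical comparators (partial least squares
    regression, random forest, successive projections algorithm wavelength
    selection), a k-fold cross-validation harness with RMSE/NRMSE/R2 reporting,
    and a synthetic scene/spectrum generator for fully reproducible benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    mixOmics,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
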