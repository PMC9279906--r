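Package: canopyspec
Title: Hyperspectral Canopy Phenotyping and Spectral Trait Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end toolkit for predicting biochemical traits (such as
    soluble solids content and pH) of plant canopies from Vis-NIR
    hyperspectral images. Reads and writes ENVI hypercubes, applies
    white/dark reference reflectance calibration, segments canopy pixels
    with the spectral angle mapper, and extracts per-plant mean spectra.
    Provides the standard chemometric pretreatments (moving window
    smoothing, Savitzky-Golay filtering, first and second derivatives,
    wavelet denoising), Kennard-Stone sample partitioning, competitive
    adaptive reweighted sampling (CARS) wavelength selection, five
    multivariate regression baselines (PLSR, LWR, MLR, ANN, SVR), and two
    purpose-built neural regressors: a multi-scale (Inception-style)
    convolutional network operating on grid-reshaped spectra and an
    expand-then-contract fully connected network, both trained with Adam
    on an RMSE objective. A synthetic canopy-spectra generator with known
    trait structure makes every pipeline stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    e1071,
    nnet,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
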