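Package: hsiQuant
Title: Hyperspectral Image Chemometrics with Squeeze-and-Excitation
    Residual Network Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end chemometric analysis of visible/near-infrared
    hyperspectral images of bulk medicinal material for simultaneous
    quantitation of several quality attributes (marker metabolites and
    moisture). Provides radiometric calibration of raw cubes against
    white and dark reference frames, foreground segmentation and mean
    spectrum extraction, Savitzky-Golay preprocessing, wavelength
    selection (CARS, SPA, UVE), classical calibration models (PLSR,
    epsilon-SVR, RBF networks), a squeeze-and-excitation residual
    network regressor with a multi-analyte head, Kennard-Stone sample
    partitioning, and the RMSE/R2/RPD/RER evaluation suite. A seeded
    synthetic-data generator renders plate images with known
    concentration ground truth so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    signal,
    e1071,
    MASS,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
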