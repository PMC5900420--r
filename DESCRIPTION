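Package: shikimap
Title: Shikimic Acid Phenotyping from Hyperspectral and Chlorophyll
    Fluorescence Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric pipeline for non-destructive estimation of
    shikimic acid accumulation in glyphosate-treated maize canopies from
    visible/near-infrared hyperspectral images and chlorophyll
    fluorescence parameter tables. Provides ENVI cube input/output,
    reflectance calibration, NIR/red band-ratio plant segmentation,
    wavelet (Daubechies-6) and scatter-correction spectral preprocessing,
    successive projections algorithm and random frog feature selection,
    NIPALS partial least-squares regression and discriminant analysis
    with SPXY sample partitioning, pixel-wise chemical concentration
    mapping, and a synthetic-data generator that reproduces the
    two-genotype by two-treatment by four-day study design so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    signal,
    EBImage,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
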