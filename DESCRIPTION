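Package: fretquant
Title: Calibration and Quantification for Semisynthetic FRET Biosensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification machinery for ratiometric and lifetime-based FRET
    biosensor experiments: hyperbolic binding-isotherm fits of plate-reader
    titrations, fluorescence-polarization direct and competition binding fits,
    pixel-wise sensitized-emission net FRET with spectral bleedthrough
    correction and ROI extraction, gel-based labeling-efficiency arithmetic,
    TCSPC multi-exponential decay fitting with amplitude-weighted lifetimes,
    and lifetime-calibration-based absolute analyte concentration inference.
    Includes seeded synthetic-data generators that emulate every input class
    (titration tables, polarization series, three-channel microscopy images,
    photon-count decay histograms) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    EBImage
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
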