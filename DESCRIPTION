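Package: siribruise
Title: Structured-Illumination Reflectance Imaging Analysis for Early
    Fruit Bruise Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for multispectral structured-illumination
    reflectance imaging (SIRI) of fruit: flat-field/dark-frame calibration,
    three-phase sinusoidal demodulation into AC and DC images, ratio-image
    (AC/DC) enhancement, median filtering, and bruise segmentation by global
    thresholding, Otsu's method, or an improved Otsu objective that is robust
    to dark-spot noise from surface pits, stems and sutures.  Includes line
    profile contrast analysis for selecting the optimal spatial frequency and
    wavelength, a seeded synthetic phantom generator with full ground truth
    for validation, and sample-level bruised/normal classification with
    accuracy reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    jsonlite,
    optparse
Config/testthat/edition: 3
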