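Package: tubequant
Title: Quantification of DNA Nanotube Growth from Fluorescence Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segmentation and length measurement of filamentous DNA
    nanostructures (DX-tile DNA nanotubes) in fluorescence micrographs,
    with growth-distribution statistics and melting-temperature detection.
    Provides a median-filter background model, Gaussian smoothing,
    automatic histogram thresholding (Otsu, Yen, Triangle), morphological
    thinning with branch-point pruning of intersecting filaments, and
    per-filament length measurement in pixels and micrometers; length
    statistics include replicate-averaged mean lengths, frequency and
    length-fraction histograms, and complementary cumulative distribution
    (CCDF) analysis against the exponential growth model. A synthetic
    micrograph generator with exact ground truth and a two-transition
    melting-curve simulator make every stage testable without raw data.
    Melting temperatures are located as maxima of the derivative of
    absorbance with temperature.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
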