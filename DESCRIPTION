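Package: fluorogel
Title: Automated Densitometry, Mass Calibration and Profile Classification
    for Fluorescent SDS-PAGE Gels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the automated analysis of multi-channel fluorescence
    SDS-PAGE gel scans: gel-region and stacking/resolving border detection,
    projection-based rotation correction, equal-width lane segmentation,
    densitometric lane profiles with rolling-minimum background subtraction,
    prominence-based band detection, molecular-weight calibration by
    piecewise log-linear interpolation of a marker ladder, conservative
    rebinning of lane profiles onto a common molecular-mass axis, absolute
    quantification of the degree of labelling from a fluorophore dilution
    series, and classification of protein-modification patterns against a
    digital reference library by squared Pearson correlation. A seeded gel
    simulator with full ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
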