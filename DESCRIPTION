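Package: hemicanopy
Title: Canopy Structure and Light Regime from Hemispherical Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating forest canopy structure and understorey
    light regime from upward-looking fisheye photographs, including the
    rectangular diagonal frames produced by smartphone fisheye lenses.
    Implements azimuthal-equidistant projection models for circular and
    diagonal images, geometric merging of an orthogonal diagonal pair into
    a pseudo-hemisphere, automatic sky/canopy thresholding (iterative
    selection on the blue channel and a colour-attribute fuzzy score),
    gap-fraction extraction on a 24-sector by 18-annulus sky grid, Canopy
    Openness, Total Gap, and annual Indirect/Direct/Global Site Factors
    under a Standard Overcast Sky and an annual sun track. A synthetic
    canopy simulator with exact ground truth supports validation and bias
    studies, and calibration utilities fit and compare linear
    transformation models between paired camera protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    jpeg,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
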