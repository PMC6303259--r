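Package: capiflow
Title: Label-Free Capillary Imaging by Erythrocyte Tracing and
    Flattened-Vessel Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing of label-free intravital movies of perfused tissue in
    which flowing erythrocytes act as intrinsic point tracers. Implements the
    full stack pipeline (frame-shuffle decorrelation, blur and aberrant-frame
    rejection, subpixel rigid registration, minimum- and average-intensity
    projection, background flattening), absorption profilometry of vessel
    cross-sections, a seeded synthetic movie generator with full ground truth,
    block-matching particle image velocimetry, and two hemodynamic models: a
    Poiseuille solver on the circle-to-stadium cross-section family of a tube
    flattened at constant perimeter, and a heterogeneous-conductivity lattice
    relaxation reproducing the flux exclusion zone around a flattened
    arteriole tip.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml,
    graphics,
    grDevices
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
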