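Package: osteogel
Title: Composition Analysis of Cell-Mineralized Fibrin Gel Constructs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Histomorphometric analysis of osteoid-like organic/inorganic
    composite gels fabricated by culturing mesenchymal stem cells in 3D
    fibrin gel. Implements RGB-ratio pixel classification of von Kossa- and
    hematoxylin/eosin-stained sections (mineral, matrix and nucleus masks,
    single-cell line profiles), conversion of stained-section area fractions
    into a four-component volume composition (mineral, matrix, cell, residual
    fibrin) via a contraction-normalised scaling factor, gel-contraction
    time-series analytics (length contraction, per-day Student t comparisons,
    plateau detection), and mineralized-vesicle morphometry (connected-
    component labelling, per-cell area ratio and mean vesicle size). A
    seeded synthetic-phantom generator provides stained-section images, gel
    shrinkage curves and vesicle masks with known ground truth so that every
    stage is testable without real micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
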