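Package: wsipath
Title: Tile-Based Whole-Slide Image Classification for Bladder Cancer
    Grading and Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete patch-based pipeline for three-way diagnostic
    classification of bladder-cancer whole-slide images (high-grade
    muscle-invasive, high-grade non-muscle-invasive, low-grade
    non-muscle-invasive): polygon annotation I/O in an ASAP-style XML
    dialect, Otsu white-background removal over a fixed region-of-interest
    grid, sliding-window and junction-point patch sampling for six tissue
    classes, a compact six-class convolutional patch classifier trained
    with a multistep SGD recipe, dense tile inference into a 6-channel
    probability heatmap at 1/32 scale, contour-based area-weighted
    slide-level confidence scoring, and an evaluation surface with
    Clopper-Pearson intervals and ROC/AUC. Ships a deterministic synthetic
    slide generator so the whole pipeline is testable end to end without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    pracma,
    stats,
    tiff,
    utils,
    xml2
Suggests:
    class,
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
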