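Package: wormvision
Title: Automated Image Analysis for C. elegans Plate Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Image-analysis engines for quantitative Caenorhabditis elegans
    phenotyping on agar plates: moving-worm counting from two-image
    time-lapse pairs for lifespan assays, multi-worm centroid tracking and
    velocity statistics from plate videos, skeleton-based body-length
    measurement from still images, and multi-threshold egg counting.
    Includes a deterministic simulator that renders sinusoidal virtual
    worms, egg plates and time-lapse pairs with ground-truth manifests so
    every engine can be validated against known truth, plus batch
    processing, tile assembly and file-based result correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
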