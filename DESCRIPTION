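Package: steatoscope
Title: Steatosis Quantification from Smartphone Microscopy Images of Liver Biopsies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies hepatic macrosteatosis from low-resolution RGB images of
    H&E-stained frozen-section liver biopsies captured through a microscope
    ocular (for example with a smartphone). Implements a non-machine-learning
    segmentation pipeline: per-image adaptive green/blue thresholding from
    histogram peaks, vignette-border exclusion, morphological noise removal,
    size/circularity rejection of tears and vascular lumina,
    distance-transform watershed separation of clustered droplets, and a
    two-pass circularity filter; converts masks to per-image and per-liver
    steatosis percentages. Also provides rater-agreement statistics (two-way
    mixed-effects intraclass correlation with F-based confidence intervals,
    Pearson correlation, ordinary least squares, clinical threshold
    disagreement counts) and a synthetic phantom generator with exact ground
    truth for end-to-end validation without real slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
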