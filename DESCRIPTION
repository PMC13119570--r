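Package: coralmorph
Title: Hierarchical Detection-to-Segmentation Morphometry for Coral Recruit Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures live-tissue surface area of single coral recruits in
    calibrated microscopy images through a hierarchical pipeline: a detector
    localises the recruit and classifies its developmental stage (early or
    late), the stage routes the image to a stage-specific promptable
    segmenter built from the bounding box plus, for early stages, four
    background points at the box-edge midpoints, and the resulting mask is
    converted to square micrometres using the pixel size embedded in the
    image metadata. Ships deterministic mock detector and segmenter
    backends, a classical thresholding segmenter, a synthetic recruit-image
    generator with exact ground truth, and a full evaluation layer (IoU,
    area ratio, auto-acceptance rate, median-area-ratio bias, stratified and
    ablation reports) so every stage of the pipeline is testable without
    trained network weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
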