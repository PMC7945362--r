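Package: stomapipe
Title: Instance Segmentation, Size Filtering and Morphometry of Stomata in
    Microscope Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A detector-agnostic pipeline for high-throughput stomata analysis
    in leaf epidermis microscope images. Provides CLAHE-based colour
    normalisation that removes colour-space bias across sample-preparation and
    imaging techniques, a pluggable instance-detector contract with a bundled
    classical baseline and a ground-truth perturbing oracle, a statistical
    false-positive filter that infers the per-image stomatal scale from
    detection confidences and areas, per-stoma morphometry (area, orientation,
    axis lengths) from boundary masks, a precision/recall/F-score and IoU
    evaluation harness, VGG Image Annotator (VIA) polygon JSON import/export,
    and a synthetic epidermis scene generator with exact ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
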