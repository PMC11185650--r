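Package: pixikit
Title: Headless Image Annotation, Measurement and Human-in-the-Loop
    Classification for Bioimages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless toolkit for bioimage analysis projects: an in-memory
    project store for multichannel z-stacked images with staged
    (commit/revert) edits, per-object binary mask annotation operators
    (geometric shapes, SLIC superpixel quick-select, flood fill, threshold),
    intensity and morphometric object measurements (area, perimeter, extent,
    equivalent diameter, sphericity, compactness, quartiles, median absolute
    deviation) with split-wise summaries and plot-ready series, a small
    resumable convolutional classifier supporting the human-in-the-loop
    labeling workflow, and interoperable import/export of images (PNG, JPEG,
    hyperstack TIFF, uncompressed DICOM), COCO annotations, instance and
    semantic masks, Zarr project archives, CSV measurement tables and
    portable model files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    jsonlite,
    png,
    jpeg,
    tiff,
    rlang
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
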