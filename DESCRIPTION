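Package: salseg
Title: Selective Level-Set Image Segmentation with Edge, Region and Saliency Forces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hybrid active-contour segmentation of 2-D grayscale or RGB
    images. A level-set function is evolved under a weighted combination of
    a Difference-of-Gaussians zero-crossing edge force, a global signed
    pressure force built from Chan-Vese style region means, and an adaptive
    saliency force, with reinitialization-free Gaussian regularization of
    the level set after every step. Supports selective (region-of-interest
    seeded) segmentation of single objects in multi-object scenes, a
    deterministic synthetic-scene generator with known ground truth, the
    standard overlap metrics (Dice, accuracy, specificity, Jaccard, F1),
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    jpeg,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
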