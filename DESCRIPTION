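Package: msiseed
Title: Multispectral Image Classification of Mechanical Damage in Sugar Beet Seeds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying mechanical processing damage in polished
    monogerm sugar beet (Beta vulgaris) seeds from 19-band multispectral
    reflectance image stacks (375-970 nm). Provides a synthetic seed image
    generator with per-pixel ground truth, multi-page TIFF stack input/output,
    Otsu-based seed segmentation, extraction of 19 shape, colour and binary
    variables per seed, a pixel-level normalized canonical discriminant
    transform that highlights damaged tissue, a factor-analytic scoring model
    with mean +/- SD per-class score ranges and contiguity correction,
    severity-max classification of ventral/dorsal image pairs, and
    confusion-matrix evaluation with per-class accuracy, false-negative and
    false-positive percentages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
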