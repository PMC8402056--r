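Package: earcount
Title: Point-Supervised Counting of Rice Ears in Quadrat Field Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts dense plant organs (rice ears/panicles) in fixed-area
    quadrat field images from point annotations alone. Implements a
    localization-counting loss over a fully convolutional segmentation
    network (image-level, point-level, watershed split and false-positive
    terms), the segmentation-to-blob inference chain, red-frame quadrat
    detection and rectification, flip/rotation augmentation with annotation
    transport, a classical image-processing baseline counter, count
    evaluation metrics (MAE, RMSE, nRMSE, accuracy rate), and a synthetic
    field-image generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    optparse,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
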