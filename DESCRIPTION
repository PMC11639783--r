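Package: sranet
Title: Self-Residual Attention Networks for Chest X-Ray Person Re-Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metric-learning toolkit for biometric person identification and
    verification from chest radiographs. Implements an attention-augmented
    convolutional embedding generator (self-residual attention blocks with
    channel and spatial gates, an attention block, and a reverse attention
    block on top of a residual-network backbone), trained as a Siamese
    triplet network with a Euclidean distance layer and hinge triplet loss.
    Includes gallery/query top-k identification, thresholded one-to-one
    verification with threshold calibration, a synthetic radiograph phantom
    generator for fully reproducible end-to-end testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
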