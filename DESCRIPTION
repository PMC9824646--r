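Package: csbnet
Title: Compressed-Domain Leaf-Disease Image Classification with a Learned
    Measurement Operator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements CSBNet, a compressed-domain image classifier in which
    a learned convolutional measurement block (the CS-Block: three 3x3
    stride-2 convolutions, a 1x1 projection to X = 192 * SR channels, and an
    up-sampling stage) replaces the sensing matrix of classical compressed
    sensing.  Classification is performed directly on the measurements, with
    no reconstruction, by an AlexNet-derived feature extractor, a channel
    attention stage (squeeze-and-excitation, efficient channel attention, or
    the convolutional block attention module), and a three-layer fully
    connected classifier.  Includes per-layer trainable-parameter accounting,
    reconstruction of unstated interior layer widths from published parameter
    totals, confusion-matrix metrics, a cross-entropy/Adam training loop with
    a sensing-rate sweep harness, and a seeded synthetic leaf-disease image
    generator so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    EBImage,
    caret,
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
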