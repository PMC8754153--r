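Package: gaincam
Title: Guided-Attention Training and Grad-CAM Supervision for Lesion
    Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for training interpretable binary lesion classifiers with
    gradient-weighted class activation mapping (Grad-CAM) and a three-stream
    guided-attention architecture: a classification stream, an
    attention-mining stream that softly erases the attended region and
    penalises residual class evidence, and a bounding-box stream that
    supervises attention maps against annotated boxes. Includes a two-stage
    training protocol with stochastic affine augmentation, a built-in
    reverse-mode differentiation engine and compact convolutional backbone,
    a synthetic lesion-image generator with a label-correlated confounder,
    and attention-localization metrics (energy-in-box, thresholded IoU,
    pointing game) for comparing models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
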