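Package: neuroseg
Title: Multi-Scale Boundary Detection and Reinforcement-Learning Gap
    Amendment for Neuronal EM Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation of neuronal membrane structures in electron
    microscopy images. Detects structure boundaries by fusing
    Laplacian-of-Gaussian zero crossings across the levels of a Gaussian
    image pyramid, then closes gaps in the detected boundary curves with a
    SARSA(lambda) walker whose moves are supervised by a locally fitted
    polynomial curve model trained by per-sample gradient descent. Includes
    the evaluation suite standard in this field (precision/recall/F-score,
    pixel error, Rand index and error, topology-aware warping error, macro
    averages) and a synthetic phantom generator producing EM-like images
    with exact ground truth and controlled gap injection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
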