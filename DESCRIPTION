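Package: spmcount
Title: Simulation, Hybrid Dataset Construction and Deep-Learning Counting
    of Nanoparticles in Surface Plasmon Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Physics-based simulator of interferometric scattering images of
    nanoparticles in surface plasmon microscopy (a propagating surface-plasmon
    plane wave interfering with decaying scattered waves), an image degradation
    pipeline (disk blur, additive Gaussian noise at a target SNR in dB), a
    hybrid labelled-dataset builder mixing pure simulations with composited
    backgrounds and particle patches, an 11-class particle-count convolutional
    network classifier with an EfficientNet-B0-style and a reduced desk-scale
    profile, and evaluation reports (row-normalised confusion matrices,
    accuracy-versus-count curves per noise level, and a peak-counting baseline).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
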