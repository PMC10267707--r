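Package: dpgen
Title: Dynamic-Pruning Group-Equivariant Networks for Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a dynamic-pruning group-equivariant convolutional
    network (DPGEN) for two-class motor-imagery EEG classification. Provides
    the finite symmetry-group algebra of the P4 (rotation) and P4M
    (rotation-mirror) groups acting on square kernels, lifting and group
    convolutions with their equivariance property, a magnitude-based dynamic
    pruning-and-splicing calculus with surrogate gradients and masked SGD,
    an alternating weight/mask training loop, a short-time-Fourier-transform
    preprocessing pipeline that turns C3/CZ/C4 epochs into stacked mu/beta
    time-frequency images, a seeded generator of ERD/ERS motor-imagery-like
    EEG trials, and classification plus compression reporting (accuracy,
    ROC/AUC, compression ratio).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
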