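Package: endocode
Title: Tissue Classification for Confocal Laser Endomicroscopy Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end classification of confocal laser endomicroscopy
    (CLE) frame streams into tissue classes (glioblastoma versus
    meningioma). Provides entropy-based pruning of uninformative frames,
    dense upright SIFT descriptors, visual vocabularies via flat and
    hierarchical k-means, feature coding by Bag-of-Words, sparse coding,
    locality-constrained linear coding and locality-constrained sparse
    coding (the latter solved by an ADMM with soft-thresholding and a fast
    K-nearest-neighbour restriction), histogram pooling, SVM classification
    under video-grouped cross-validation, and sliding-window majority
    voting over predicted label streams. Includes a synthetic two-class
    endomicroscopy texture generator so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    tiff,
    optparse
Config/testthat/edition: 3
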