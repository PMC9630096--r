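Package: chemoarch
Title: Cortical Chemoarchitecture and Connectome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links cortical neurotransmitter receptor and transporter density
    profiles to the structural and functional organization of the brain.
    Provides containers for parcellated receptor atlases and parcel geometry;
    receptor similarity, distance-decay fits and principal receptor gradients;
    spatial-autocorrelation-preserving spin permutation and degree- and
    edge-length-preserving connectome rewiring nulls; communicability-based
    structure-function coupling with receptor augmentation; full-subset
    dominance analysis for multilinear receptor models; partial least squares
    correlation between receptor and regional feature matrices; and
    distance-dependent cross-validation. A synthetic data generator with
    planted ground truth makes every stage testable without external imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
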