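Package: surgseg
Title: Unsupervised Temporal Segmentation of Robot-Assisted Surgery Procedures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Off-line temporal clustering of multivariate system data streams
    (console and patient-side kinematics plus binary system events) from
    robot-assisted surgery into clinically relevant tasks. Implements aligned
    cluster analysis (ACA) and its hierarchical variant (HACA) — kernel k-means
    over temporal segments with a dynamic time alignment kernel and dynamic
    programming boundary search — together with spectral clustering and
    Gaussian mixture model baselines, Hungarian-matched segmentation accuracy,
    per-task precision/recall, a proportional-duration baseline, and a
    synthetic pseudo-procedure generator for fully reproducible evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    jsonlite,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
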