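Package: phosphonet
Title: De Novo Dissection of Kinase and Phosphatase Signaling Networks from
    Sparse Phosphoproteomic Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs kinase/phosphatase to substrate signaling networks
    from sparse, censored phosphoproteomic abundance matrices and infers
    per-sample enzyme activity by signalon enrichment. Mutual information
    between peptide rank profiles is estimated by a hybrid adaptive
    partitioning estimator that treats censoring below the limit of detection
    as informative, indirect edges are pruned by a signal-transduction-aware
    data processing inequality, bootstrap consensus networks are scored by a
    Poisson model, and per-regulator signalons drive analytic rank-based
    enrichment with crosstalk (pleiotropy) correction and hierarchical
    phosphostate/activity-level integration. A seeded synthetic-data generator
    with known ground truth supports calibration and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    limma,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    caret,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Network, NetworkInference, Proteomics, SystemsBiology
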