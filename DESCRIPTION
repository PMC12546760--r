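Package: neurosbi
Title: Simulation-Based Inference for Conductance-Based Neuron Models with
    Transcriptomic Linkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits single-compartment Hodgkin-Huxley-based neuron models to
    current-clamp recordings by simulation-based inference. Provides a fast
    conductance-based simulator with 13 inferable biophysical parameters, an
    extractor for 23 electrophysiological summary features, large prior
    simulation campaigns, neural posterior estimation with a masked
    autoregressive normalizing flow made robust to model misspecification by
    noise-augmented training, and a rank-2 sparse reduced-rank regression
    stage that predicts the inferred biophysical parameters from ion-channel
    gene expression. Includes synthetic-data generators emulating Patch-seq
    style cohorts so the whole pipeline can be exercised without external
    archives.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    glmnet,
    nnet,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
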