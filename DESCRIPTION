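Package: ppada
Title: Physics-Informed Pretraining and Adversarial Domain Adaptation for Leaf Trait Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of leaf reflectance and transmittance with the
    PROSPECT-D generalized plate model, Latin-hypercube generation of synthetic
    spectra-trait corpora, and a two-stage deep transfer-learning workflow
    (physics-informed pretraining of a residual spectral encoder followed by
    adversarial domain adaptation with gradient reversal and contrastive
    attention) for estimating chlorophyll content, equivalent water thickness
    and leaf mass per area from 400-2400 nm leaf reflectance. Includes a PLSR
    baseline, leakage-safe standardization, stratified k-fold and
    leave-one-dataset-out validation protocols, and a benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    pracma,
    lhs,
    data.table,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
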