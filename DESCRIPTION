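Package: grnstab
Title: Stability of Gene Regulatory Networks Built with Sparse
    Autoregressive Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers gene regulatory networks from short, equally spaced
    gene-expression time series with first-order multivariate vector
    autoregression (MVAR) under ridge, lasso and elastic-net penalties,
    and quantifies how reproducible the inferred structure is. Provides a
    preferential-attachment simulator of scale-free regulatory topologies,
    generation of synthetic expression series with controlled innovation
    and perturbation noise, leave-one-out cross-validated penalty tuning
    by cyclic coordinate descent, approximate t-based significance tests
    for penalized coefficients with false-discovery-rate control,
    Hamming-distance network and edge stability criteria, consensus
    (stable) networks, and orchestration of replicate benchmarks and
    signal-to-noise perturbation studies.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    glmnet,
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
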