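Package: coxsmbpls
Title: Supervised Sparse Multi-Block Partial Least Squares for Multi-Omics
    Survival Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits supervised Cox sparse multi-block partial least squares
    (Cox-sMBPLS) survival models that integrate gene expression, genotype and
    DNA methylation blocks. Right-censored survival times are reweighted by
    inverse censoring probability weights derived from a Kaplan-Meier estimate
    of the censoring distribution, cross-block redundancy is removed by
    residualizing cis-regulatory QTL pairs (eQTL, meQTL, eQTM), and sparse
    block direction vectors are obtained by univariate soft-thresholding.
    Retained latent components enter a final Cox proportional-hazards model,
    yielding sparse multi-omics modules associated with survival. Includes
    time-dependent ROC/AUC estimators (Harrell's C, Uno and Chambless
    cumulative/dynamic AUC, incident/dynamic AUC), cross-validated tuning, a
    synthetic multi-omics survival simulator and an elastic-net Cox benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    survival,
    glmnet,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
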