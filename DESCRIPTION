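Package: svbench
Title: Benchmarking Surrogate-Variable Normalization for RNA-Seq Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation benchmark for RNA-seq normalization workflows.
    Generates gene-by-sample count matrices from a per-gene negative
    binomial model with multiplicative binary and continuous batch
    effects and a binary biological factor; implements library-size
    scale factors (upper quartile, TMM, RLE), CPM and gene-length
    normalizations, latent-artifact estimators (permutation-based and
    asymptotic surrogate-variable counting, two-step surrogate variable
    construction, residual RUV, variance-threshold PCA), and two
    differential-expression workflows (testing on batch-adjusted data
    versus including estimated factors in the design matrix) with
    moderated t-statistics. Evaluation metrics cover the rate of
    correctly estimated latent-factor counts, Euclidean distance to a
    batch-free baseline, and averaged empirical type-I error, exposing
    the degrees-of-freedom cost of post-normalization testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    edgeR,
    sva,
    MASS,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    limma,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: RNASeq, Normalization, BatchEffect, DifferentialExpression,
    Software
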