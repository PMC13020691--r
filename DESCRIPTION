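Package: stabpipe
Title: Bootstrap Stability Selection for Dimensionality-Reduction and
    Clustering Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hyperparameter optimization for unsupervised learning chains
    that couple dimensionality reduction (kernel PCA, non-negative matrix
    factorization, t-SNE) with clustering (K-means, spectral). Candidate
    hyperparameter combinations are scored by the mean adjusted Rand index
    between cluster assignments of consecutive bootstrap resamples and by
    the mean Davies-Bouldin index, then selected by a two-stage
    top-ARI / minimum-DBI rule. Final cluster membership is produced by
    10-fold cross-validation with Hungarian label alignment. Includes an
    effect-size-controlled Gaussian-mixture simulator for benchmarking
    pipelines, plus evaluation metrics (adjusted Rand index, Davies-Bouldin
    index, Cramer's V concordance, decision-tree interpretability accuracy,
    and logistic-regression AUROC outcome association).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    kernlab,
    Rtsne,
    clue,
    rpart,
    pROC,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
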