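Package: mtgsel
Title: Multi-Task Ensemble Gene Selection for Tumor Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint gene selection and binary tumor classification for
    high-dimension, low-sample gene expression data.  Repeatedly subsamples
    the training set into m overlapping tasks and fits them jointly by
    multi-task logistic regression under an l2,1 row-group penalty, so that
    genes are selected consistently across tasks.  The convex objective is
    solved by proximal gradient descent (block soft-thresholding) with
    backtracking line search; predictions average task logits before the
    logistic link.  Includes 5-fold cross-validation for the penalty weight,
    L1 and elastic-net single-task baselines sharing the same solver, ReliefF
    and mRMR filter baselines, a multivariate-normal simulation generator
    with planted relevant genes, and a repeated-split experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
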