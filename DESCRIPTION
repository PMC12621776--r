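Package: chromcast
Title: Chromatin State Imputation from Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Imputes genome-wide chromatin state annotations (18-state
    ChromHMM-style segmentations at 200-bp resolution) for samples that
    have only RNA-seq gene expression available. For every sample in a
    reference compendium with matched expression and chromatin states, a
    multinomial lasso model is trained on one-hot encoded states of the
    expression-nearest reference samples; predictions for a new sample
    ensemble the models of its nearest references. Includes expression
    preprocessing (protein-coding filtering, quantile normalization,
    log2 transform), majority-state and k-nearest-neighbour baselines,
    cross-validation fold construction and two-stage hyperparameter
    selection, an evaluation suite (stepwise-interpolated AUPRC, AUROC,
    accuracy, size-weighted Jaccard and F1 averages, probability
    calibration, genomic fold enrichment, pairwise sample
    relationships, per-state signal averaging), and a synthetic
    compendium generator for end-to-end benchmarking without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    Matrix,
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    optparse,
    pROC
Config/testthat/edition: 3
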