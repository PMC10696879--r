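Package: atacscreen
Title: Hash-Demultiplexed Single-Nucleus ATAC Chemical Screen Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for pooled chemical screens read out by
    single-nucleus ATAC-seq with nuclear hash labels. Implements chi-squared
    hash demultiplexing against an ambient debris background, species-mixing
    collision evaluation, per-cell QC and TF-IDF/LSI embeddings of binarized
    accessibility matrices, simulated-doublet scoring, dose-response logistic
    differential accessibility with pooled Benjamini-Hochberg correction,
    four-parameter log-logistic viability fits, pseudodose trajectories
    (principal-graph geodesics, negative-binomial spline smoothing, trend
    classification), motif trend enrichment, elastic-net prediction of
    expression dose coefficients from promoter and distal motif features,
    and FRIP-by-dose interaction tests. A synthetic-data generator with
    planted ground truth exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    igraph,
    glmnet,
    minpack.lm,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    cluster
Config/testthat/edition: 3
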