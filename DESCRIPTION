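Package: tmecorr
Title: Spatial Cross-Correlation Analysis of Multiplexed Tissue Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-cell analysis of cyclic immunofluorescence (CyCIF) tissue
    microarray data with a focus on spatial relationships in the tumor
    microenvironment. Provides quality control for segmented cell feature
    tables (DNA coefficient-of-variation and autofluorescence filters),
    Gaussian-mixture marker gating and hierarchical lineage assignment,
    k-nearest-neighbor spatial cross-correlation between cell-type pairs with
    exponential-decay curve fitting and per-patient interaction
    classification, latent Dirichlet allocation over cellular-neighborhood
    token documents, and immune gene-signature scoring of expression
    matrices with quartile-stratified group comparisons. Includes a
    synthetic-tissue generator that plants spatial cross-correlation of known
    strength and decay length, QC defects, and group-structured expression
    matrices, so that every stage of the pipeline can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    mclust,
    minpack.lm,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
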