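Package: glomint
Title: Integrative Bulk and Single-Nucleus Transcriptomics of Kidney Compartments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for integrating laser-capture-microdissected
    glomerular and whole-cortex bulk RNA-seq with single-nucleus RNA-seq in
    mouse models of diabetic kidney disease. Provides a synthetic-data
    generator emulating the study design (three phenotype groups in two
    kidney compartments plus a labelled single-nucleus matrix with planted
    cell-type markers), negative-binomial Wald differential expression with
    median-of-ratios normalization and Benjamini-Hochberg control, Stouffer
    gene-set perturbation scoring, single-nucleus quality control and the
    twofold cell-type specificity rule, and superimposition of compartment
    DEG sets onto cell types, together with PCA, Venn and RPKM group
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    ggplot2
Config/testthat/edition: 3
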