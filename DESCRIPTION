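Package: festsc
Title: Antigen-Specific T Cell Clonotype Calling and Single-Cell Companion Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics for identifying antigen-specific T cell clonotypes from
    peptide-stimulation TCR-beta sequencing (FEST-style expansion testing with
    Fisher exact tests, Benjamini-Hochberg FDR, odds-ratio and well-distribution
    criteria, including a triplicate mode), and for characterizing their
    transcriptional programs in coupled scRNA-seq/TCR-seq data: single-cell QC
    gating with density-trough CD8 selection and CDR3 barcode linking,
    cluster-level pseudobulk PCA with a canonical-correlation permutation test,
    a cell-type composition ratio test with a multinomial Monte-Carlo null,
    binned-control gene-set scores and rank-sum marker calling, and a
    pseudotime differential-expression likelihood-ratio permutation test.
    Ships seed-deterministic synthetic-data generators with known ground truth
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    splines,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
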