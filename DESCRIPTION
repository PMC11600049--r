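Package: sctme
Title: Comparative Single-Cell Tumour Microenvironment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a comparative single-cell RNA-seq
    analysis pipeline for contrasting tumour immune microenvironments across
    patient groups (multiple vs. solitary primary lung cancer, tumour vs.
    adjacent normal tissue). Provides cell-level quality control and
    normalisation, Wilcoxon/AUC marker detection with marker-based cluster
    annotation, cluster-by-group odds-ratio preference testing with
    Benjamini-Hochberg correction, copy-number scoring with malignant-cell
    classification, arm-level subclone collapsing and clonal trees,
    AUC-preranked gene-set enrichment analysis with permutation FDR,
    ligand-receptor interaction filtering, module scoring, and
    signature-based survival stratification (Kaplan-Meier, log-rank, Cox).
    A synthetic-data generator plants the statistical structure each stage
    assumes so the whole pipeline is testable without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    ape,
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
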