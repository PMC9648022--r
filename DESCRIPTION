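Package: cervstage
Title: Stage-Wise Expression Meta-Analysis and Biomarker Evaluation for
    Cervical Carcinogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sequential gene-expression study of
    cervical malignant transformation (Normal -> LSIL -> HSIL -> SCC):
    per-dataset differential expression against normal tissue, cross-study
    direction-consistent DEG unions, Spearman stepwise-gene detection and
    the DEG/stepwise intersection, hypergeometric over-representation of
    gene-set collections, nine-method protein-interaction network centrality
    ranking with cross-dataset consensus hub calling, immunohistochemistry
    scoring (layer, intensity, H-score) with full diagnostic evaluation
    (exact confidence intervals, exact McNemar, Cohen's kappa), and
    prognostic survival analysis (maximally selected cutpoints,
    Kaplan-Meier/log-rank, multivariate Cox, IPCW time-dependent AUC).
    Ships synthetic-data generators that emulate the study design so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
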