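Package: vulnscreen
Title: Pathway-Level Genetic Vulnerabilities from Perturbation Viability Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of genome-scale loss-of-function (RNAi/CRISPR) viability
    screens across cell-line panels. Calls hits with batch-wise robust Z
    scores, scores annotated gene sets (protein complexes) for bimodal
    cell-line sensitivity using exact one-dimensional 2-means clustering,
    assesses significance by global permutation with Storey q-value FDR
    control, benchmarks the clustering with a leave-one-out ROC procedure,
    discovers sensitivity blocks de novo with Large Average Submatrix (LAS)
    biclustering plus hypergeometric gene-set enrichment, and provides an
    alternative per-line hypergeometric product score. Includes a synthetic
    screen generator with planted ground truth and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
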