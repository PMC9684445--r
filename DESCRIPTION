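Package: serumiR
Title: Serum miRNA Biomarker Discovery and TF-miRNA Regulatory Network
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering circulating miRNA
    diagnostic biomarkers from case/control expression profiles and for
    dissecting their regulatory context. Covers quantile normalisation and
    moderated-t differential expression with Benjamini-Hochberg control,
    single-line-regulation (NSR) and transcription-factor-percentage (TFP)
    biomarker scoring on a disease-specific miRNA-mRNA network, ROC/Youden
    diagnostics and logistic multi-marker panels, consensus filtering of
    predicted miRNA targets across databases, MCODE dense-module detection
    in protein-protein interaction networks, and enumeration and
    classification of TF-miRNA-gene feed-forward loops with hub ranking.
    Ships a synthetic-data generator with planted ground truth so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
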