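Package: DCIScurve
Title: Principal-Curve Pseudotime and Progression Biomarkers for Micro-Dissected DCIS RNA-seq
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for ordering micro-dissected breast lesion RNA-seq samples
    (normal epithelium, benign, atypia, ductal carcinoma in situ, invasive
    ductal carcinoma) along a disease-progression continuum. Implements TMM
    normalisation and log2-CPM transformation, an iterative correlation-based
    sample quality filter with full bookkeeping, moderated differential
    expression with patient blocking, panel-based PCA with a Hastie-Stuetzle
    principal curve and arc-length projection (the principal curve projection,
    PCP), single-sample gene-set enrichment (ssGSEA) and sliding-window
    over-representation scans along the ordering, residual-resampling bootstrap
    trend fits, and a rule-based marker decision tree stratifying patients into
    progression-hazard groups. Includes a negative-binomial synthetic-cohort
    generator with a latent progression coordinate, patient random effects,
    outcome-linked bimodal marker genes and injected low-quality samples, used
    for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Matrix,
    limma,
    edgeR,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
biocViews: Transcriptomics, GeneExpression, RNASeq, QualityControl,
    DifferentialExpression, GeneSetEnrichment, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
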