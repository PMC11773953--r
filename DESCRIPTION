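Package: mirpancor
Title: miRNA Target Prediction from Pan-Cancer Expression Correlation
    Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Predicts microRNA (miRNA) target genes from multi-cohort
    (pan-cancer) expression data. Per-cohort Pearson correlations between
    every miRNA and every gene, computed over co-expressing samples only,
    form a per-pair feature vector; curated interaction databases supply
    binary labels; an ensemble of gradient-boosted classifiers trained on
    repeatedly downsampled versions of the overwhelming negative class
    calls significant miRNA-gene pairs by consensus frequency; calls are
    validated against held-out databases, differential expression after
    miRNA perturbation, and correlation-direction concordance. A
    synthetic multi-cohort generator with planted, signed miRNA-gene
    effects makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
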