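Package: qgexar
Title: Predicting Endocrine-Disruption Activity from Gene-Expression Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Qualitative Gene expression Activity Relationship (QGexAR)
    modelling: classifies chemicals as active or inactive against endocrine
    endpoints (estrogen and androgen receptor binding, thyroid receptor
    antagonism) from L1000-style differential gene-expression z-score
    signatures measured in two cell lines. Provides a seeded synthetic
    signature generator with planted informative genes, the data-assembly
    rules (conflict resolution, TAS-based profile deduplication, gene-tier
    filtering, shared validation split), MultiSURF relief-based feature
    selection, a class-weighted model zoo evaluated by nested cross-validation
    with balanced-accuracy model selection, two-cell-line consensus
    prediction, a cosine-similarity 3-nearest-neighbour applicability domain,
    and Kruskal-Wallis feature-importance reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    glmnet,
    ranger,
    xgboost,
    e1071,
    nnet,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
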