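Package: lexscreen
Title: Lexico-Semantic Network Screening for Early Low-Language Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-child lexico-semantic networks from expressive
    vocabulary checklists (nouns linked by shared semantic features),
    derives graph-theoretic vocabulary-structure measures (mean path
    length, clustering, degree, betweenness, harmonic centrality),
    assembles them with vocabulary-size percentiles, early grammar items
    and demographics into a 14-predictor table, and trains nested
    cross-validated random-forest classifiers with minority oversampling
    (SMOTE) and drop-one feature-importance pruning to predict later
    low-language outcomes. Includes a synthetic-data generator emulating
    two longitudinal checklist datasets, clinical screening evaluation
    (sensitivity, specificity, balanced accuracy, predictive values,
    likelihood ratios) and internal/external validation harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    ranger,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
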