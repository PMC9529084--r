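Package: matriscreen
Title: Pan-Cancer Prioritisation of Matrisome Genes from Copy Number,
    Expression and Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A multi-stage screen for prioritising extracellular-matrix
    (matrisome) genes across cancer cohorts. Counts deep deletion and
    high-level amplification events in GISTIC-thresholded copy-number
    matrices, selects the most altered fraction of genes, filters them for
    concordant tumour-versus-normal differential expression, screens
    survival by percentile-stratified log-rank tests and Cox proportional
    hazards, combines expression and survival breadth into a rank-sum gene
    score, and validates candidates through Spearman correlation, stage
    ANOVA, co-occurrence odds ratios and degree-based hub ranking. Includes
    a seeded multi-cancer cohort simulator with planted driver genes so
    every stage of the screen can be verified against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
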