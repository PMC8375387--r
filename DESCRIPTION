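Package: faimer
Title: Rank-Weighted Single-Sample Gene-Set Scoring and Cohort Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Derives candidate "mediated" gene sets from a two-group
    differential expression comparison (SAM-style moderated statistic with
    permutation FDR, fold-change gating, Fisher/Benjamini-Hochberg
    over-representation), scores gene sets per sample with a rank-weighted
    single-sample method (FAIME-style), and quantifies the ability of the
    resulting set-score profiles to separate disease from control cohorts
    via cumulative hypergeometric overlap tests, principal-component-level
    ROC/AUC classification, and a random-gene-set resampling null. Includes
    a synthetic microarray-like data generator so every stage is testable
    without external downloads, plus readers/writers for expression
    matrices, GMT gene-set collections, group assignments and gene
    annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
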