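Package: rectalCR
Title: Genomic Correlates of Complete Response to Neoadjuvant Chemoradiation in Rectal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort-level analysis of pre-treatment somatic mutation data from
    rectal cancers treated with neoadjuvant chemoradiation, contrasting complete
    responders (CR) with incomplete responders (ICR). Implements MAF-style
    variant ingestion with depth/allele-fraction filtering and tumor mutation
    burden, propensity-score matching-weight balancing with an iterative
    standardized-difference check and a weighted Welch t-test, gene-level
    frequency comparison and pairwise co-occurrence/mutual-exclusivity networks
    by Fisher's exact test, group-specific significance classification from
    external q-values, and a logistic complete-response prediction pipeline
    (bivariate screening, count-feature construction, Tjur R-squared/AIC model
    selection, training-set classification metrics). A synthetic-cohort
    generator with known confounding, planted co-occurring gene pairs, and a
    known response mechanism makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
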