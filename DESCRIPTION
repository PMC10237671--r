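Package: twiskit
Title: Transcriptome-Wide Gene-Gene Interaction Studies and Set Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exhaustive transcriptome-wide interaction studies (TWIS) using
    genetically imputed gene expression. Imputes per-gene expression from
    SNP dosages and linear expression weights, residualizes phenotype and
    expression on covariates, tests all gene pairs with a three-term
    interaction regression under linkage-disequilibrium-aware pair filters,
    combines cohorts with sample-size-weighted Z-score meta-analysis, and
    aggregates pairwise interaction Z-scores into gene-set enrichment tests
    (E-TWIS) with chi-squared and resampling nulls. Includes a synthetic-data
    generator and a calibration suite covering power under expression
    prediction error, LD-driven false positives, genome-wide alpha
    determination from minimum p-value order statistics, and comparison of
    residualization strategies against the full covariate-interaction model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    fgsea,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
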