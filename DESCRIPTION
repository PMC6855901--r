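Package: gravidmet
Title: Differential Abundance Pipeline for the Early-Pregnancy Plasma Metabolome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for untargeted plasma metabolomics
    comparisons of pregnant (8-16 weeks of gestation) and non-pregnant women
    from total-ion-count abundance data. Implements run-day median scaling,
    detection filtering, limit-of-detection imputation, storage-time decay
    correction, quantile normalization, Mann-Whitney differential abundance
    under a dual false-discovery-rate / fold-change criterion, pathway
    over-representation by Fisher's exact test, Spearman correlation networks
    and hierarchical clustering of metabolites, gestational-age trend testing,
    and sensitivity re-analyses. Ships a synthetic-cohort generator that
    emulates the statistical structure of such studies (left-censoring,
    run-day batches, storage decay, correlated sub-pathway blocks,
    gestational-age slopes) with full ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    limma,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
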