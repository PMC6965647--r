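Package: chaperomics
Title: Differential-Connectivity Analysis of Chaperome Interactomes from
    AP-MS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for chemical-bait affinity-purification
    mass-spectrometry (AP-MS) interactomics of the cellular chaperome.
    Implements MS1-intensity preprocessing (within-sample quantile
    normalization, minimal-intensity imputation, log10 transform),
    per-protein differential-connectivity (DC) testing with
    threshold-profile classification into disease- and control-specific
    pools, construction and annotation of combined protein-protein
    interaction (PPI) reference networks with quality-control exclusion
    rules, hypergeometric over-representation and permutation gene-set
    enrichment statistics, interactome gene-set enrichment analysis
    (iGSEA) over the first-degree PPI neighborhood of each chaperome
    member, stepwise mouse-to-human ortholog mapping, and a fully seeded
    synthetic-data generator with planted ground truth for end-to-end
    validation.
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
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fgsea,
    jsonlite,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
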