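Package: ltmscreen
Title: Expression-Stratified Screening for Circadian Clock-Coupled Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Genome-wide in-silico screen that ranks genes by how strongly
    their natural expression variation across unordered population samples
    tracks circadian clock strength. For each candidate gene, samples are
    split into expression quantile groups; per group, clock strength is
    quantified by the mean normalized coefficient of variation (nCV) of a
    clock gene set and by the Mantel cross-product similarity of the
    clock-gene correlation matrix to a reference matrix. Correlating these
    measures with group mean expression yields per-gene scores (LTMpre,
    LTMori, LTMabs) that flag candidate clock-coupled genes without any
    sample timestamps. Includes preparation utilities (TPM conversion,
    quantile normalization, isoform collapse, low-expression filtering,
    winsorization), multi-dataset meta-integration, random-background
    normalization, and a seeded synthetic-population generator with planted
    clock-coupling for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    limma,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
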