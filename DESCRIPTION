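Package: tempomir
Title: Time-Resolved Integration of miRNA and mRNA Expression for
    Senescence Subtyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for integrating time-course miRNA and mRNA
    sequencing data across cellular senescence subtypes. Provides
    median-of-ratios normalization, a moderated negative-binomial Wald test
    for per-time-point differential expression, fuzzy c-means soft clustering
    of temporal profiles, multi-source miRNA-target annotation filtering,
    Spearman anti-correlation pairing of regulators with candidate targets,
    hypergeometric target enrichment within temporal clusters, UpSet-style
    exclusive set intersections, cross-subtype comparison, and hub-miRNA
    ranking. Includes a synthetic-data generator with planted temporal
    prototypes and repressor-target structure for end-to-end validation.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
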