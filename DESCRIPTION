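Package: ruralindex
Title: Rank-Based Microbial Indices, Discrete-FDR Differential Abundance,
    and Paired-Omics Coupling Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and applying signed microbial indices from
    16S amplicon sequence variant (ASV) feature tables. Implements a
    rank-mean permutation test for two-group differential abundance with
    discrete false-discovery-rate (dsFDR) control, per-sample log-rank-ratio
    index scoring (rural/health style dysbiosis indices) with cross-cohort
    ASV sequence matching, the supporting preprocessing filters (prevalence,
    contaminant f-score, rarefaction, metabolite normalization and
    cleaning), age-bin matched cohort comparisons, coefficient-concordance
    and exact-binomial consistency statistics, and a permutation
    significance test for shared variation between paired omics blocks via
    first-component two-block partial least squares. Includes a
    Dirichlet-multinomial synthetic cohort generator emulating
    rural/urban/disease group structure so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
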