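Package: popexpress
Title: Population-Diversity Diagnostics for Linear Expression Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how population-differentiated variants
    affect genetically predicted gene expression from PrediXcan-style linear
    models. Provides readers and writers for expression-model weight tables,
    dosage matrices and predicted-expression matrices; the weighted-sum
    prediction engine with a rank-based inverse normal transform; a
    genome-wide two-proportion allele-frequency differentiation test; a
    four-parameter simulation grid over variant number, minor allele
    frequency, differentiated-variant proportion and weight group; an
    allele-frequency-driven empirical gene-expression reference panel with
    Kolmogorov-Smirnov stability and population comparisons; and an
    evaluation module that scores user predictions against the panel by
    percentile rank and empirical reference intervals. A synthetic-data
    generator emulates model, frequency, genotype and prediction inputs with
    controlled population structure.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DBI,
    RSQLite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
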