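Package: prscape
Title: Cross-Population Polygenic Risk Scores from Catalog Associations and
    Population Allele Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Harmonizes GWAS-catalog-style association tables into a per-SNP
    risk model with averaged odds-ratio weights, derives per-population
    effect-allele counts from genotype VCFs or aggregated frequency tables,
    scores per-population effect-allele enrichment against the pooled
    remainder with a signed -log10 Fisher exact-test statistic, computes a
    normalized polygenic risk score for individuals and its expected value
    for populations, and regresses population-level disease incidence and
    mortality on the score and on hormone and vitamin-D covariates. A
    Balding-Nichols simulator generates catalog rows, diverged population
    frequencies, Hardy-Weinberg genotype panels and epidemiology tables with
    known ground truth so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    pheatmap,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
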