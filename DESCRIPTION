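Package: psger
Title: Parent-Specific Gene Expression from Reciprocal Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of allele-specific read counts from reciprocal crosses
    between two lineages to detect parent-of-origin, lineage-of-origin, and
    cross-asymmetric expression biases. Selects informative SNPs from parental
    genotypes (homozygous mother, discordant haploid father), filters per-SNP
    allele counts, fits a per-transcript linear mixed model with parent,
    lineage and their interaction as fixed effects and SNP and library as
    random intercepts, controls the false discovery rate by Benjamini-Hochberg,
    and classifies transcripts by direction-consistent allelic ratios. Includes
    the Storer-Kim exact unconditional two-proportion test, hypergeometric
    list-overlap tests, a 2x2 chi-square, and a synthetic reciprocal-cross
    data generator with known truth for calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
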