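Package: xciescape
Title: Quantifying Escape from X-Chromosome Inactivation from Allelic Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies escape from X-chromosome inactivation (XCI) in bulk
    RNA-seq samples exhibiting skewed XCI. Starting from gene-level haplotype
    read counts, the package computes allele-specific expression and allelic
    fold change, estimates each sample's degree of XCI skewing from the XIST
    allelic ratio, derives skew-adjusted escape scores as min-max rescaled
    residuals of a pooled linear model of allelic fold change on skew, and
    calls per-gene per-tissue escape status. Downstream analyses cover
    intra-donor tissue sharing of escape, inter-individual consistency,
    between-tissue and between-cell-type comparisons, reference-annotation
    benchmarking, and twin-pair concordance of escape. A seeded generative
    simulator of allelic counts with ground truth supports validation and
    power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
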