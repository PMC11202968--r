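Package: hapbiva
Title: Haplotype-Block Diplotypes, Population-Genetic Screening, and
    Specific Bioelectrical Impedance Vector Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end toolkit linking haplotype-block genotypes to body
    composition phenotypes. Provides screening statistics for biallelic
    variant panels (minor allele frequency, Weir-Cockerham and Hudson Fst,
    two-locus EM linkage disequilibrium, contiguous-run LD-block detection,
    Tajima's D), rule-based diplotype calling from unphased genotypes under
    a same-phase assumption, specific bioelectrical impedance vector
    analysis (BIVA) with tolerance and confidence ellipses, Hotelling T2
    two-sample comparison and Mahalanobis distance, capsaicin/PROP sensory
    scoring, covariate-adjusted diplotype-phenotype association, and a
    synthetic-cohort generator with known ground truth for validating every
    stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
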