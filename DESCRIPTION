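Package: autozyg
Title: Inbreeding Measures, Inbreeding Depression and Runs-of-Homozygosity
    Genome Scans for Livestock Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify inbreeding in pedigreed, SNP-genotyped
    livestock populations and to estimate its consequences for quantitative
    traits. Implements pedigree inbreeding coefficients (Meuwissen-Luo),
    pedigree completeness, sparse inverse numerator relationship matrices,
    genomic inbreeding measures (genomic-relationship self-relationship,
    SNP homozygosity, runs of homozygosity over a grid of minimum lengths),
    a repeated-records animal model with REML variance components for
    inbreeding-depression regression, and a sliding-window genome scan of
    run-of-homozygosity effects with additive-SNP correction, region
    clustering and an expected-false-positive FDR. A gene-dropping
    simulator generates pedigrees, genotypes and phenotypes with known
    genome-wide and locus-specific autozygosity effects so the whole
    pipeline is testable end to end.
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
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    lme4,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
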