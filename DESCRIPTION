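Package: methleakr
Title: Detecting and Removing Genotype Leakage from DNA Methylation Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing whole-genome bisulfite sequencing (WGBS)
    methylation tracks for embedded genetic variation before open data
    release. Simulates strand-specific WGBS cohorts with CpG-disrupting
    SNPs and indirect meQTLs, screens for CpG sites whose "methylation"
    is static within individuals but variable between them, fits the
    linear genotype-methylation model with per-genotype predictive
    accuracy, calls diploid genotypes at CpG sites from strand-specific
    bisulfite evidence, quantifies SNP confounding of pairwise
    differential methylation, and sanitizes methylation tracks with a
    per-site accounting report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    vcfR,
    rtracklayer,
    IRanges,
    GenomicRanges,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
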