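Package: iidmr
Title: Inter-Individual Differentially Methylated Region Analysis for Twin
    Methylome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls inter-individual differentially methylated regions (iiDMRs)
    from Illumina-style beta-value methylation matrices using an
    adjacency/threshold/direction rule (directionally consistent absolute
    methylation differences of at least 5% at two or more adjacent probes
    within 500 bp), quantifies their temporal stability across array
    platforms and their biological-versus-technical reproducibility by
    permutation, integrates methylation differences with H2A.Z and
    H3K4me3/H3K27me3 chromatin profiles and FPKM expression tables, and
    tests enrichment of iiDMR probes across genomic features, embryonic
    stem cell chromatin states, housekeeping genes and ageing-associated
    probes. Ships a synthetic monozygotic-twin cohort generator with a
    machine-readable truth table so the whole pipeline is testable without
    external data.
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
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
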