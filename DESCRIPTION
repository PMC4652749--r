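Package: antisensr
Title: Chromatin Architecture Associated with Nascent Antisense Transcription
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genome-wide analysis pipeline linking nascent antisense
    transcription to promoter and gene-body chromatin architecture in budding
    yeast. Genes are classified into five groups by strand-specific nascent
    read counts (NET-seq) in a 300 bp window downstream of the sense TSS;
    chromatin tracks (nucleosome occupancy, histone H3 and its modifications,
    promoter factor ChIP) are then profiled around the TSS per class,
    correlated position-by-position with sense and antisense transcription,
    and summarised as nucleosome-depleted-region (NDR) sizes, histone-turnover
    distributions and promoter-factor enrichment tables. A mutant-versus-
    wild-type module regroups genes by antisense class shifts and computes
    difference metagenes. A seeded synthetic-data generator reproduces the
    statistical structure of the published datasets so every stage can be
    validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
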