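Package: enrichdiff
Title: Differential Histone-Mark Enrichment Analysis for Two-Genotype ChIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for comparing a promoter-associated histone
    mark (H3K4me3) between two genotypes from paired treatment/input ChIP-seq
    coverage. Provides read-quality summary arithmetic, a simplified
    window-Poisson peak caller over fixed-step wiggle tracks, strand-aware
    classification of peaks against gene annotation (upstream, intragenic,
    downstream, intergenic), CpG-island association, chromosome-normalised
    peak densities, metagene profiles, gene calling by TSS proximity, unique
    and preferential (amplitude-fold) differential-enrichment detection,
    integration with a differential-expression table, ChIP-qPCR
    percent-of-input and relative-expression utilities, and a seeded
    synthetic-data generator that plants a two-genotype peak landscape with
    full ground truth for recovery testing. All user-facing functions take
    and return tibbles so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
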