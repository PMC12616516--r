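Package: darkgenome
Title: Dark-Genome Analysis of Long-Read Brain Sequencing Call Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tidy analysis layer for the repeat-rich "dark" fraction of the
    human genome as seen by long-read brain sequencing. Takes caller-output
    tables (retrotransposon insertion calls, non-allelic homologous
    recombination junctions, multi-sample structural-variant VCFs, per-sample
    CpG methylation frequency tables) and provides the downstream statistics:
    singleton and L1-endonuclease insertion filtering, windowed NAHR
    enrichment, group-unique structural-variant logic, beta-binomial
    differential CpG methylation with DMR aggregation and areaStat,
    metachromosome meta-bin profiling, and a length-preserving permutation
    region-overlap test. A seeded synthetic-data module emulates every input
    format with planted ground truth so the full pipeline is testable without
    access to restricted human data.
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
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
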