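Package: ribotile
Title: Abundance-Guided Antisense Probe Design for Microbiome rRNA Depletion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Taxonomy-neutral design of antisense oligonucleotide pools for
    enzymatic (RNase H) depletion of ribosomal RNA from microbiome total-RNA
    sequencing libraries. Reads are quality-filtered and binned by k-mer
    containment into rRNA, host, and retained categories; per-base coverage of
    rRNA references is piled up from alignments; contiguous high-depth regions
    are extracted, ranked by median depth, pooled across learning samples,
    collapsed at an 80 percent pairwise-identity threshold, and tiled with
    fixed-length antisense probes at a configurable inter-probe gap. Includes
    an in-silico depletion evaluator (interval-overlap surrogate), Shannon
    diversity and total-sum-scaling utilities, and a seeded synthetic-community
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicAlignments,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    readr,
    rlang,
    Rsamtools,
    S4Vectors,
    ShortRead,
    stats,
    stringr,
    tibble,
    tidyr,
    vegan,
    withr
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
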