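Package: dikaryotriage
Title: Coverage, Homology and Mitogenome Triage for Dikaryotic Fungal
    Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Post-assembly triage for fungal genome assemblies sequenced
    from dikaryotic (functionally diploid) mycelium. Classifies contigs
    into coverage groups from per-contig read counts to diagnose diploid
    character, detects allelic contig pairs by unique k-mer anchoring and
    banded global alignment, identifies mitochondrial contigs by joint
    GC-deviation and over-representation criteria, detects and bisects
    tandem-duplicated mitogenome contigs into circular chromosomes,
    assesses single-copy marker duplication, screens proteins for class I
    and class II terpene-synthase catalytic motifs, and performs
    two-species pan-genome accounting. Ships a ground-truthed synthetic
    dikaryotic genome generator so every stage is testable without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
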