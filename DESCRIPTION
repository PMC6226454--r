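Package: famscan
Title: Genome-Wide Gene-Family Scanning, Phylogeny and Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for genome-wide characterization of a plant gene
    family, built around the 20-member potato Hsp70 chaperone family.
    Provides consensus-motif identification of family members with an
    empirical permutation E-value, protein characterization (ORF length,
    molecular weight, isoelectric point), neighbor-joining phylogeny with
    bootstrap supports and subfamily cutting, exon/intron structure and
    splice-phase reports, Smith-Waterman based tandem versus segmental
    duplication classification, FPKM expression normalization and
    average-linkage clustering, delta-delta-Ct qPCR regulation calls, and a
    seeded synthetic potato-like genome generator so the whole pipeline runs
    end-to-end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    generics,
    Rcpp,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
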