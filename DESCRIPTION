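Package: decaylens
Title: Transcriptome Characterization of 3'-5' RNA Decay Mutants Across the
    Oocyte-to-Embryo Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for identifying putative cytoplasmic
    exosome (Ski complex) decay targets from a staged wild-type versus mutant
    RNA-seq time course. Provides differential expression calling with a
    simplified negative-binomial exact test and an expression filter with
    DEG/unchanged classification rules, overlap analysis of DEG sets
    against expression-matched resampled control sets with Yates-corrected
    chi-squared tests, metagene 100-bin coverage profiles and per-region
    (5'UTR/CDS/3'UTR) read-density ratios for detecting 3' coverage bias,
    transcript-feature comparisons (region lengths, codon adaptation index
    with a random-sequence background), and a negative-binomial synthetic-data
    generator that emulates the two-genotype, three-period, three-replicate
    study design so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
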