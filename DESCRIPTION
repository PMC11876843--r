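Package: motifgrammar
Title: Discovery of Transcription-Factor Motif Grammar in Tissue-Specific Enhancers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering combinatorial transcription-factor (TF)
    binding syntax in tissue-specific enhancers. Scans enhancer sequences with
    position-weight-matrix (PWM) log-odds models parsed from JASPAR or TRANSFAC
    count matrices, builds a binary sequence-by-TF binding matrix, mines
    frequent TF co-occurrence itemsets and association rules (Apriori; support,
    confidence, lift), detects adjacent ordered triads of TF binding sites with
    arrangement counts, Fisher's exact arrangement tests and inter-site spacing
    statistics, scans genome-wide cis-regulatory module (CRM) catalogs for an
    ordered triad pattern, classifies CRMs into conservation-depth categories
    from phastCons-style per-base scores, intersects CRMs with epigenomic
    interval tracks to shortlist a core set, and generates fully synthetic
    inputs with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
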