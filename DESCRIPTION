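Package: gbekit
Title: Guide Design and Amplicon Quantification for Glycosylase Base Editors
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for working with deaminase-free glycosylase-based base
    editors (gTBE, gCBE, gGBE) and their deaminase-based counterparts.
    Provides a registry of editor chemistries, PAMs and editing windows;
    sgRNA design for splice donor/acceptor disruption (exon skipping),
    premature-termination-codon introduction and bypass, and intron-split
    reporter restoration; a naive mismatch-tolerant off-target scanner;
    amplicon deep-sequencing outcome quantification (per-position conversion
    frequencies, indel frequency, product purity, T-to-S ratio, editing
    window and 5'-motif profiles); a mutagenesis-library planner for UNG
    engineering; and a synthetic-read and toy-gene-model generator with a
    ground-truth ledger so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
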