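Package: pretRNAends
Title: Classification and Quantification of Pre-tRNA 3' Ends from Targeted RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the 3' termini of intron-containing tRNA
    precursors from targeted small-RNA sequencing libraries. Reads are
    quality-filtered, stripped of the 5' library adapter, reverse-complemented
    into sense orientation and collapsed; each unique read is locally aligned
    to per-gene precursor references (leader + gene body with intron +
    trailer), its genomically non-encoded 3' suffix is extracted under a
    maximal-templated-extent rule, and the read is classified as
    trailer-containing, exactly end-processed, carrying a partial or full
    non-templated CCA, oligo-adenylated, or 3' trimmed. Per-gene category
    percentages and CCA shares among end-processed precursors are tabulated,
    and a simulator generates libraries with known ground truth for
    validation. Includes a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    yaml,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
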