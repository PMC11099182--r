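Package: bcrtrace
Title: Clonal-Family Inference and Signature Projection for Plasma-Cell Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking plasma-cell recruitment from paired single-cell
    B-cell receptor (BCR) and transcriptome data. Implements paired-chain
    clonal-family inference from CDR3 nucleotide identity with donor/V/J/length
    keys, reconstruction of gapped germline FR1-CDR1-FR2-CDR2-FR3 sequences and
    somatic-hypermutation rates, matching against antigen-specific reference
    clonotypes ("public" clones), repertoire diversity and cluster-overlap
    statistics with a permutation null, and per-cell pre-ranked gene-set
    enrichment of time-point signatures onto plasma-cell transcriptomes.
    Ships seeded simulators for AIRR-style rearrangement tables and
    negative-binomial UMI count matrices with planted ground truth, so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
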