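Package: flowalign
Title: Flow-Space Assisted Local Alignment for Pyrosequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Local sequence alignment that exploits the raw flowgram signal of
    454-style pyrosequencing reads. Extends the Smith-Waterman-Gotoh algorithm
    with homopolymer up-call and down-call corrections whose penalties are
    proportional to the flowpeak deviation required to justify the corrected
    homopolymer length. Includes flowgram base calling, pre-computed
    correction penalty tables, an SSAHA-style k-tuple database index with a
    diagonal seeding heuristic, readers and writers for SFF and flowgram-FASTA
    (FFASTA), a seeded noisy-flowgram read simulator, and evaluation harnesses
    for decoy-recovery and read-mapping experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
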