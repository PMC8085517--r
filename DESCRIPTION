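Package: pseudoexonr
Title: Detection, Mapping and Splice-Site Scoring of Pseudoexon-Activating
    Deep Intronic Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the molecular diagnosis of pseudoexon inclusion
    events caused by deep intronic single-nucleotide variants. Detects
    inserted segments in observed transcript or amplicon sequences
    relative to a reference mRNA, maps them to their intron of origin,
    infers the causal variant at the created or strengthened splice
    sites, annotates DNA/RNA/protein consequences (HGVS-style intronic
    offset coordinates, premature termination codons, frameshift start),
    and scores donor and acceptor splice-site windows with
    position-weight-matrix, inhomogeneous first-order Markov, and
    maximum-entropy models. Includes a deterministic synthetic-data
    generator producing toy genes, genomes, variants and spliced
    transcripts so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
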