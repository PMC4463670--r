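Package: mamiR
Title: Small RNA-Seq miRNA Identification, IsomiR Typing and Two-Library
    Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-library small RNA sequencing studies:
    adapter trimming and quality filtering of raw reads, collapsing into
    unique tags, one-mismatch genome mapping, ncRNA annotation and removal,
    conserved miRNA identification against miRBase-style mature and hairpin
    references, isomiR decomposition (5'/3' length variants, non-templated
    3' additions, seed substitutions), miRNA:miRNA* duplex detection,
    reads-per-million normalization with an exact conditional count test for
    differential expression, stem-loop qPCR 2^-ddCt validation with
    hierarchical clustering, and seed-match target scanning. A seeded
    synthetic small-RNA read generator with full ground truth drives every
    stage offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
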