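Package: notchscreen
Title: Notch Target Discovery by Fold-Change Screening, GO Enrichment
    and Promoter Motif Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reimplements, as a tested pipeline, a microarray screen for
    transcriptional targets of Notch signalling in the early embryonic
    forebrain: per-chip percentile normalization of one-colour intensity
    arrays, signed fold-change computation with an absolute cutoff,
    hypergeometric Gene Ontology over-representation testing with
    Benjamini-Hochberg adjustment, and a cross-species promoter scan for
    strict and degenerate IUPAC binding-site motifs (E-box, N-box, and
    the 7-mer ASCL1/HEY and ASCL1/NHLH1 antagonist signatures) with
    presence-based conservation calls. Ships a synthetic-data generator
    that plants known fold changes, an enriched GO term and conserved
    promoter motifs so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
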