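Package: motiphy
Title: Degenerate Motif Evolution Across Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing short degenerate sequence motifs across a
    protein family and its phylogeny: a motif grammar with a scanner and a
    variant classifier, alignment-column conservation and sequence-logo
    information content, homologue detection by local alignment under
    identity and query-coverage thresholds with presence/absence
    phylogenetic profiling, Fitch small parsimony for motif gain/loss
    mapping on a tree, and a simulator that evolves protein families along
    a tree with implanted motifs and designed variant switches so every
    stage can be checked against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
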