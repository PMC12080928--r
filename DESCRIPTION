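Package: taxoforce
Title: Taxogenomic Genus Delineation and Environmental Forcing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-based prokaryotic taxonomy and pangenome ecology.
    Computes pairwise genomic relatedness indices (average amino acid identity,
    percentage of conserved proteins, and fragment-based average nucleotide
    identity) from reciprocal-best-hit protein and fragment searches; delineates
    genera by enumerating all threshold-stable single-linkage partitions of a
    similarity matrix and ranking candidate threshold intervals against a
    reference grouping; partitions pangenome gene-content variation into
    environmental and phylogenetic components with canonical correspondence
    analysis of gene presence/absence constrained by habitat; and calls
    habitat-specific gene clusters by ordination scores or habitat exclusivity.
    Includes seeded simulators of similarity matrices and pangenomes with
    planted ground truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    ape,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    MASS,
    withr
Config/testthat/edition: 3
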