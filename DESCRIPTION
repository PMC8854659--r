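Package: arscan
Title: Lineage-Specific Accelerated Region Detection from Multiple Alignments
Version: 0.1.0
Authors@R: person("arscan", "maintainers", email = "arscan@example.org", role = c("aut", "cre"))
Description: Detects genomic elements with lineage-specific accelerated
    substitution rates from a multiple sequence alignment and a neutral
    phylogenetic model. Conserved elements are regularized into fixed-width
    fragments, each fragment is scored with a constrained likelihood-ratio
    test for a rate increase on a designated branch or subtree (Felsenstein
    pruning under a reversible nucleotide model), empirical p-values are
    obtained from parametric simulation of the neutral model, and calls are
    made after Benjamini-Hochberg false-discovery-rate correction.
    Accelerated elements are assigned to genes within a configurable flank
    and gene lists are tested for a distribution shift of element q-values.
    Includes a seeded synthetic-data generator that emits a complete
    miniature study (tree, neutral model, MAF alignment, conserved elements,
    gene models, gene lists, truth table) for desk-scale validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
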