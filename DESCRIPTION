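Package: tcrconv
Title: Convergence Analysis of T Cell Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Repertoire", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pinpointing antigen-driven convergent selection in
    T cell receptor (TCR) beta-chain repertoires. Implements a V(D)J
    recombination generative model used both as a Monte-Carlo null and as
    a synthetic-data simulator, a neighbor-enrichment (ALICE-style) test
    that flags CDR3 amino-acid sequences with more Hamming-distance-1
    neighbors than the recombination null predicts, similarity-graph
    cluster construction with GML export, specificity annotation against
    a VDJdb-style database with cluster-level label propagation,
    repertoire clonality statistics, and a replicate-based negative
    binomial exact test for differential clonotype expansion between
    culture conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    igraph,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
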