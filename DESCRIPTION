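Package: clusterm
Title: Conserved Protein Complex Detection Across Multiple PPI Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies protein complexes conserved across two or more
    protein-protein interaction (PPI) networks by a divide-and-conquer
    strategy: cross-network protein spines seed personalized-PageRank
    neighborhoods, each neighborhood is refined to the exact
    minimum-conductance set around the seed (a binary fractional program
    solved by parametric minimum cuts), and the union of the per-network
    sets is greedily pruned to maximize within-network interaction density
    plus cross-network sequence homology. Includes readers and writers for
    edge lists, BLAST bit-score similarity, spines, complexes and GO
    annotations (GAF); a full evaluation suite (neighborhood affinity,
    fraction matched, complex-wise Sn/PPV/Acc, maximum matching ratio, mean
    normalized entropy, coverage); degree-preserving rewiring for
    robustness analysis; a grid-search parameter sampler; and a synthetic
    benchmark generator with planted conserved complexes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    optparse,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
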