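Package: gatraj
Title: Pseudotime Trajectory Inference by Genetic Algorithm on Cell Permutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orders single cells along a pseudotime trajectory by minimising a
    rank-based polynomial BIC cost over the space of cell permutations with a
    genetic algorithm (inversion mutation, Poisson-cut crossover with bipartite
    matching repair, quarter selection). Includes cluster-wise ordering joined
    into branching lineage trees via endpoint distances and a minimum spanning
    tree, a subsampling scheme with nearest-neighbour score propagation and
    principal-curve consensus for large cell numbers, a Gamma-Poisson
    trajectory simulator with three dropout regimes, and accuracy metrics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    cluster,
    data.table,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
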