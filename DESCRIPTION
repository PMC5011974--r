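Package: netdom
Title: Dominating-Set Analysis of Directed Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identification of candidate key-player and master-regulator genes
    in directed gene regulatory networks via minimum dominating sets (MDS) and
    minimum weakly-connected dominating sets (MCDS). Provides an exact
    integer-programming route (branch-and-bound 0/1 backend with iterative
    generation of connectivity cuts), a three-phase greedy colouring heuristic,
    strongly/weakly connected component decomposition with a density-based
    component selection rule, a hypergeometric enrichment test, seeded random
    digraph generators for benchmarking, brute-force certification oracles,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
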