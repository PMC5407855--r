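Package: relmap
Title: Reconstructing Map-Like Relational Structure from Neural Adaptation and Response Times
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the latent graph structure of discrete
    relational knowledge from pairwise neural-adaptation signals and
    response times. Implements graph-theoretic proximity metrics (link
    distance, Euclidean layout distance, communicability via the matrix
    exponential, the successor representation, and shortest paths weighted
    by experienced transition counts), the stimulus-sequence designs of a
    statistical-learning experiment (constrained random walks and
    transition-balanced Eulerian-circuit sequences), synthetic cohort
    generators, competitive regression and distance-contrast analyses,
    multidimensional-scaling map recovery, and a permutation null over
    connected graph topologies with a planar line-crossing test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    MASS,
    Matrix,
    igraph,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
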