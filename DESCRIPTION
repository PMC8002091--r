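Package: moldesign
Title: Inverse Molecular Design with a Two-Layered Graph Model and Integer Programming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Infers chemical graphs with a prescribed property value by inverting a
    feed-forward neural-network regressor over interpretable two-layered graph
    descriptors. A hydrogen-suppressed chemical graph is split, for a branch-parameter
    rho, into an interior (the part left after rho rounds of leaf stripping) and
    an exterior (a collection of height-bounded fringe trees). Descriptors count
    interior edge-configurations and r-isomorphism classes of fringe trees, a ReLU
    network is trained on them, and a mixed-integer linear program that simulates both
    the graph construction under a user-written topological specification and the
    network forward pass recovers chemical graphs attaining a target value. A dynamic
    programming step counts and enumerates feature-vector-equivalent isomers.
    Includes a synthetic data generator, SDF input/output, and a command-line
    interface covering the five pipeline stages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    ChemmineR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
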