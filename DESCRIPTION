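Package: netcollide
Title: Synchronous Message-Passing Dynamics with Destructive Collisions on
    Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation of communication dynamics on directed
    mesoscale brain networks. Implements synchronous message passing under
    information-spreading (copy to every outgoing edge) and random-walk
    (one uniformly chosen outgoing edge) routing, with fully destructive
    signal collisions and an optional let-one-pass rule. Provides readers,
    validators and filters for tabular connectome matrices, Treves-Rolls
    population and lifetime sparseness measures of the resulting activity,
    degree-preserving (Maslov-Sneppen) and Erdos-Renyi null models, and an
    experiment layer for load sweeps and empirical-versus-randomized
    ensemble comparisons with Welch t tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
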