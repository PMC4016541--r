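Package: critfrag
Title: Critical-Fragment Screening of Mass-Action Biochemical Mechanisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Graph-theoretic linear stability screening of biochemical
    mechanisms with mass-action kinetics. A mechanism is represented as a
    bipartite digraph on species and reaction nodes; fragments (sets of k
    species paired with a multiset of k reactions) are enumerated together
    with their subgraphs (species-disjoint covers by cycles and edges) and
    assigned integer weights. Fragments of negative weight ("critical
    fragments") are necessary for multistability, and their existence at
    sub-maximal orders signals the potential for oscillations or Turing
    instability. A symbolic verification layer reconstructs the
    characteristic-polynomial coefficients of the parametrized Jacobian from
    the enumerated fragments and checks them against principal-minor
    expansions. Ships parsers for a plain-text mechanism dialect, packaged
    example mechanisms, a seeded random-mechanism generator, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
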