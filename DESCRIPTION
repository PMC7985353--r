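Package: tseqnet
Title: Temporal Sequences and Delay-Aware Signaling Dynamics on Geometric Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates discrete, delay-aware signaling dynamics on directed
    geometric networks such as the C. elegans connectome. Signal propagation
    delays are derived from Euclidean distances between node positions and a
    conduction velocity; nodes are excitatory or inhibitory, fire on a single
    incoming signal, and obey a refractory period. The package extracts
    Temporal Sequences (causal walks of individual signals from a stimulated
    start node to designated end nodes), compares sets of such sequences with
    a greedy in-order similarity measure, decomposes them into a basis of
    one-time and repeating sequences via tandem-repeat compression, counts
    motorneuron class interactions, and provides degree-preserving edge-swap,
    Gilbert, and block-embedding graph null models, together with seeded
    synthetic network fixtures and brute-force oracles for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
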