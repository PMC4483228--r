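Package: DBGbubbles
Title: Polynomial-Delay Enumeration of Length-Bounded Bubbles in De Bruijn Graphs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Detects candidate alternative-splicing events and small variants in
    RNA-seq data without a reference genome, by enumerating bubbles in the
    de Bruijn graph of the reads. Implements a polynomial-delay binary-partition
    algorithm for enumerating all (s,t,alpha1,alpha2)-bubbles (two internally
    vertex-disjoint paths with per-path length bounds) for a fixed source in a
    non-negatively weighted digraph, built on truncated Dijkstra shortest-path
    trees with selectable priority queues. Includes the de Bruijn graph
    front-end (k-mer counting with an abundance filter, all-overlap arc
    construction, linear-path compression, biconnected-component
    decomposition), a unit-capacity max-flow generalization to d pairwise
    internally vertex-disjoint paths, seeded synthetic-data generators, and
    exhaustive brute-force oracles for validation on small instances.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    igraph,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'WeightedDigraph-class.R'
    'graph-core.R'
    'graph-io.R'
    'dbg-build.R'
    'sssp.R'
    'bubble-classes.R'
    'bubble-enum.R'
    'd-bubble.R'
    'synthetic.R'
    'oracles.R'
    'sequence-io.R'
    'zzz.R'
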