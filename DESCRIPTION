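Package: graphmsm
Title: Markov State Models of Adjacency Dynamics in Molecular Contact Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grained analysis of biomolecular dynamics through dynamic
    contact graphs. Trajectories (multi-model PDB or plain XYZ tables) are
    reduced to one representative atom per residue and converted, via a
    Euclidean distance cut-off, into a time-ordered sequence of undirected
    graphs stored as an initial snapshot plus batches of edge additions and
    removals. The adjacency matrix of every ordered k-vertex tuple is encoded
    as an integer id and maintained incrementally under the edge stream;
    consecutive ids form Markov transition counts that are pooled, per vertex,
    into a global row-stochastic transition matrix whose stationary
    distribution yields a conformational entropy. Entropy differences between
    runs (e.g. ligand-free versus ligand-bound) and root-mean-square
    fluctuations provide per-residue flexibility profiles. Includes seeded
    random dynamic-graph and synthetic-trajectory generators, a text stream
    format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
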