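Package: isomgen
Title: Exhaustive Generation of Constitutional Isomers by Canonical Augmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exhaustive, duplicate-free generation of all connected,
    valence-valid constitutional structures (Kekule multigraphs) matching a
    molecular formula, optionally constrained to contain one or more
    non-overlapping prescribed substructures. Structures are enumerated by
    McKay-style canonical augmentation on element-colored multigraphs: bonds
    are added one order at a time and a child structure is kept only when the
    canonical deletion of its canonically last bond recreates its parent, so
    every isomorphism class is produced exactly once. Hydrogens are implicit;
    multi-valence elements (N 3/5, P 3/5, S 2/4/6) are handled through a
    valence-state dictionary with per-state bond-order pattern rules.
    Includes MDL SDF (V2000) input and output, substructure matching for
    posterior filtering, and a brute-force reference enumerator for
    verification on small formulas.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ChemmineR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
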