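Package: sarlattice
Title: Stereochemistry-Aware Graphical Analysis of Analog Series
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts analog series from compound sets supplied as SD files,
    determines the maximum common substructure (MCS) of each series, performs
    symmetry-consistent R-group decomposition with indexed substitution sites,
    and organizes structure-activity relationship (SAR) information into
    layered graphs: the complete graph over all substitution-site
    combinations, its reduced form without empty nodes, and per-subset
    R-group trees in which stereoisomers are resolved as individual leaves
    carrying incremental stereo-group indices. Includes a deterministic
    synthetic analog-series generator and brute-force oracles so the whole
    pipeline is testable from scratch, selectivity views comparing node
    statistics between two targets, series merging, and GraphML/DOT/JSON
    exports with layout hints.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: OpenBabel command-line tool (obabel) for 2D structure
    generation in the fixture generator
Config/testthat/edition: 3
biocViews: Cheminformatics, StructuralPrediction, Visualization
RoxygenNote: 7.3.3
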