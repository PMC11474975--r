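Package: pocketdyn
Title: Trajectory Analysis of Protein Binding-Pocket Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for analysing molecular-dynamics trajectories of
    enzymes with deep active-site channels, such as acetylcholinesterase.
    Implements binding-pose clustering from reciprocal residue-fragment
    minimum distances, essential-dynamics principal component analysis of
    main-chain coordinates with elbow-criterion conformational clustering,
    Monte-Carlo channel (gorge) radius profiling, hydration-site water
    occupancy, and per-residue molecular-mechanics interaction-energy
    decomposition.  Reads and writes PDB, GRO and DCD topology/trajectory
    files and ships deterministic synthetic-system generators used as its
    test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
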