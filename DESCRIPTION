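Package: pathtree
Title: Tree-Based Sampling of Protein Conformational Transition Paths
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Connects two structures of a protein by growing a tree of
    physically-realistic backbone conformations.  Structural deformations
    are proposed by molecular fragment replacement over a trimer phi/psi
    configuration library and filtered by the Metropolis criterion under a
    15-step proportional cooling schedule with an optional reactive
    (window-based) temperature controller.  Selection of tree nodes for
    expansion is biased over a 1-D grid on the lRMSD-to-goal progress
    coordinate (QUAD, LINEAR, UNIFORM and COMBINE weighting schemes) and,
    optionally, a 3-D ultrafast-shape-recognition projection grid that
    steers growth away from over-sampled regions.  Includes a pluggable
    coarse-grained five-term energy function, post-run analytics (tree
    depth, path breadth, reference-structure proximity, pseudo-free-energy
    profiles along a delta-lRMSD coordinate), PDB backbone I/O, and a
    synthetic toy-transition generator for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
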