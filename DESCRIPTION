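Package: netzoom
Title: Zoomable Reduction of Nonlinear Biochemical Reaction Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces nonlinear ODE models of biochemical reaction networks by
    proper lumping of fast state variables based on apparent conservation
    relations, and keeps the reduced and original models linked ("zoomed")
    through symbolic fraction parameters. Provides exact integer left null
    space computation for conserved moieties, fast/slow partitioning of
    reaction networks, construction and validation of proper lumping schemes,
    symbolic derivation of fraction parameters from quasi-steady-state and
    conservation relations, Jacobian-corrected reduced dynamics, trajectory
    back-translation, and quantitative validation of the reduction via
    relative-difference measures and parameter robustness scans. Includes a
    small exact multivariate rational-function kernel used for all symbolic
    derivations, a declarative model file format, and an SBML subset importer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    igraph,
    stats,
    utils,
    xml2
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
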