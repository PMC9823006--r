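Package: csptitr
Title: Chemical Shift Perturbation Titration Analysis for Protein-Ligand
    Binding by NMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of protein-observed NMR titrations from 2D 1H-15N
    HSQC peak lists: peak tracking across titration points by scaled
    nearest-neighbour matching, combined amide chemical shift perturbation
    (CSP) computation with sigma-threshold residue classification,
    dissociation constant estimation by nonlinear least squares on the
    two-state ligand-depletion binding isotherm, and mapping of perturbed
    residues onto crystal structures. Includes a synthetic titration
    generator with full ground truth so the entire pipeline can be
    validated by simulation, readers and writers for Sparky-style peak
    lists and NMR-STAR chemical shift tables, multi-chain C-alpha
    superposition statistics, and a permutation test for spatial
    clustering of perturbed residues.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
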