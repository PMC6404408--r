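Package: fibrilmech
Title: Structure-Based Coarse-Grained Mechanics and Thermodynamics of Protein Fibrils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A C-alpha bead, structure-based (Go-like) coarse-grained model for
    cross-beta protein fibrils. Builds native-contact topologies from PDB
    structures via the heavy-atom overlap criterion, classifies contacts as
    intrachain, interchain or intersheet, and runs overdamped Langevin dynamics
    with three constant-speed mechanical protocols: tensile stretching, shear
    and spherical-tip nanoindentation against a repulsive base plane. Analysis
    routines turn the recorded force series into elastic moduli (tensile and
    transverse Young's moduli, shear modulus) by stress-strain and Hertzian
    fitting, and temperature scans yield native-state probabilities, folding
    temperatures, RMSD and RMSF profiles. A generator for synthetic cross-beta
    fibrils supports download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
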