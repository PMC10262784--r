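Package: mdtk
Title: Comparative Analysis of Molecular Dynamics Trajectories of
    Kinase-Substrate Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Toolkit for comparative analysis of molecular dynamics
    trajectories of two-chain protein complexes, built around the analyses
    used to contrast a kinase fold with bound substrate under alternative
    variants: multi-model PDB input/output with an atom-selection
    mini-language, weighted Kabsch superposition, RMSD/RMSF profiles,
    mass-weighted normalized covariance of residue motions, DSSP-style
    secondary-structure assignment with occupancy statistics, Shrake-Rupley
    solvent-accessible and buried surface area, geometric hydrogen-bond
    counting, Ramachandran and inter-residue distance series with moving
    averages, Quality-Threshold conformational clustering with
    reference-structure labeling, and cluster-frequency-weighted interaction
    energetics.  A synthetic-trajectory generator with planted fluctuation
    amplitudes, inter-residue correlations, and two-state conformational
    mixtures provides ground truth for every analysis stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    graphics,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
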