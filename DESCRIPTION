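Package: gamdl
Title: Gaussian Accelerated Molecular Dynamics, Deep Learning, and Free
    Energy Profiling of Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated workflow for analysing enhanced-sampling
    simulations of inhibitor-bound kinases: Gaussian accelerated molecular
    dynamics (GaMD) boost-potential mathematics exercised with a Langevin
    integrator on analytic model potentials, cumulant-expansion energetic
    reweighting into free energy landscapes over distance and dihedral
    reaction coordinates, residue contact-map featurization, a compact
    convolutional neural network for conformational-state classification
    with saliency-based discovery of class-discriminative residue
    contacts, structural dynamics analysis (superposition, RMSD, RMSF,
    principal component analysis, hydrogen-bond occupancy), and
    MM-GBSA-style binding free energy bookkeeping.  A synthetic-data
    module generates multi-state conformational ensembles with designed
    inter-domain contact patterns so the full pipeline runs end to end
    without external trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
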