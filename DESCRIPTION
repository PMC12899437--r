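Package: gagfes
Title: Ring Pucker and Glycosidic-Linkage Free-Energy Surfaces for
    Glycosaminoglycans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how pyranose ring pucker and sulfation shape
    the free-energy surface of glycosidic linkage torsions (phi, psi) in
    glycosaminoglycan carbohydrates. Implements Cremer-Pople ring puckering
    transforms with canonical conformer naming and idealness scoring, the
    ring-dihedral restraining potential used to pin iduronate pucker states,
    extended-system adaptive biasing force (eABF) accumulation with CZAR
    free-energy-gradient estimation and spectral Poisson integration on a
    periodic (phi, psi) grid, landscape analysis (minima, basin segmentation,
    minimax saddle barriers, basin extents, replicate convergence), four-atom
    least-squares superposition with bond-vector divergence metrics, and
    multi-model PDB ingestion with carbohydrate linkage discovery. A seeded
    overdamped Langevin sampler on designed periodic two-basin potentials
    provides desk-scale synthetic ground truth so every stage of the pipeline
    is testable without molecular dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
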