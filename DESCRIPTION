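Package: poseRank
Title: Rescoring and Ranking of Rigid-Body Protein-Protein Docking Poses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rescoring framework for rigid-body protein-protein docking
    ensembles. Computes per-pose attributes - a contact-based interface
    symmetry score for homo-dimers, cumulative interface-probability
    scores from residue-level interface predictions, a residue-pair
    docking-potential score over side-chain and backbone interaction
    sites, and an externally supplied energy term - standardizes them
    per target, and ranks poses with an interface-RMSD-supervised
    regression model (RBF-kernel support-vector regression for
    homo-dimers, linear regression for hetero-dimers). Includes the full
    evaluation suite (interface RMSD, native-contact fractions, a
    Matthews-correlation pairwise contact score, success-rate and
    hit-count curves) and a synthetic benchmark generator producing toy
    monomers, C2-symmetric dimers, decoy ensembles at controlled
    interface RMSD, probability tables of tunable accuracy and
    correlated energy columns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    e1071,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
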