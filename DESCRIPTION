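Package: hitlead
Title: Hit-to-Lead Virtual Screening, Field-Based 3D-QSAR and Binding
    Pharmacology
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational stages of a small-molecule
    hit-to-lead campaign against the STAT3 SH2 domain: 2D hashed-path
    fingerprints with Tanimoto and scaffold-containment screening, 3D
    pharmacophore distance-bin fingerprints with 0-100 similarity ranking,
    rigid common-scaffold alignment, Gaussian-kernel field grids (H-bond
    donor, hydrophobic, electron-withdrawing, negative-ionic channels),
    NIPALS partial least squares QSAR with leave-k-out cross-validation,
    four-parameter logistic IC50 fitting, microscale-thermophoresis F_norm
    extraction and law-of-mass-action KD fitting, Cheng-Prusoff Ki
    conversion, and cross-tabulation of differentially expressed genes
    against prior STAT3/STAT1 regulation annotations. Includes seeded
    synthetic-data generators with emitted ground truth for closed-loop
    recovery testing, and a seeded end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    minpack.lm,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
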