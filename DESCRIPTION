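Package: ensift
Title: Ensemble Structural Interaction Fingerprints for Post-Docking
    Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-docking analysis of ensemble virtual screening
    experiments. Encodes ligand-receptor complexes as per-residue
    nine-bit structural interaction fingerprints (SIFt), averages them
    over ensembles of receptor conformations into per-ligand profiles,
    classifies actives against inactives or decoys with a soft-margin
    linear support vector machine evaluated by the Matthews correlation
    coefficient and AUROC, and sweeps the number of receptor
    conformations included in the profile to quantify how conformational
    coverage affects screening performance. Includes activity curation
    (Ki/IC50 thresholding, fingerprint clustering with centroid picking,
    property-matched decoy selection) and a synthetic-data generator for
    toy 3D complexes and noisy multi-conformation fingerprint datasets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    bio3d,
    e1071,
    ChemmineR
Suggests:
    ChemmineOB,
    kernlab,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
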