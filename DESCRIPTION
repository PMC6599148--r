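Package: occludeR
Title: Chimeric Templates and Conformational-State Diagnostics for
    LeuT-Fold Transporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building two-template ("chimeric") homology-modeling
    templates of LeuT-fold neurotransmitter:sodium symporters such as the
    human serotonin transporter, and for the analyses that surround such a
    modeling study: hash-domain (TM3/TM4/TM8/TM9) superposition and
    rigid-body segment repositioning, model quality-control filtering
    (Ramachandran classes, steric clashes, ion-site coordination, score
    cascades), average-linkage clustering of docking poses with
    Kelley-penalty cluster-number selection and interaction fingerprints,
    conformational-state diagnostics (extracellular and intracellular gate
    distances, chi1 rotamers, hash-superposed helix tilt angles, RMSD
    series, normalized distributions), and compartmentalized
    pathway-hydration analysis (vestibule/site water counts and
    frame-averaged occupancy grids).  A synthetic-fixture generator builds
    ideal helices, two-state toy transporters with planted transforms,
    hydration frames, and toy trajectories with planted time courses, so
    every stage is testable without external depositions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
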