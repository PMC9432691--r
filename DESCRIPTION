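Package: inospho
Title: Inositol Polyphosphate Stereochemistry and Phytase Specificity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the positional specificity of phytases
    (myo-inositol hexakisphosphate phosphohydrolases) from achiral HPLC
    product profiles. Enumerates and names myo-inositol phosphate
    stereoisomers, groups them into enantiomer co-elution classes, builds and
    simulates sequential dephosphorylation networks with phosphate
    accounting, infers ranked initial attack positions and positional
    exclusions from peak tables, resolves enantiomer ambiguity with evidence
    from a stereospecific kinase assay, and provides supporting assay
    analytics: molybdenum-blue phosphate calibration, specific activity,
    substrate-inhibition kinetics fitting, pH/thermal/storage activity
    profiles, qPCR fold-change analysis, sequence-motif classification of
    histidine acid phytases, and a ligand-pocket distance rule on protein
    structures. Includes a seeded synthetic-data generator so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    Matrix,
    jsonlite,
    bio3d,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
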