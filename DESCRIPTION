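Package: repeatfold
Title: Design and Plausibility Auditing of Tandem-Repeat Protein Structure Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probing how protein structure predictors behave on
    perfect tandem-repeat sequences. Generates repeat sequences from
    secondary-structure propensity pools, forges parametric beta-solenoid,
    alpha-helix and coil decoy structures with injectable implausible
    features and pLDDT annotation, reads and writes PDB/mmCIF with the
    AlphaFold-family pLDDT conventions, audits models for implausible
    features (buried same-charge stacks, surface hydrophobics, steric
    clashes, poor 3D/1D environment profiles), classifies folds
    geometrically, flags confident-but-implausible models, and compares
    models across ranks and prediction methods with Kabsch RMSD and
    TM-score.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    seqinr,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
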