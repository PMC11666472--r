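Package: sentencode
Title: Voxel-Wise Encoding Models of Sentence-Level Semantic Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the brain encodes sentence-level semantic
    structure with voxel-wise encoding models. The package builds balanced
    noun-verb-noun stimulus designs under category, role and run-scheduling
    constraints; featurizes sentences into binary predictor matrices at several
    levels of relational specificity (bag-of-nouns, broad and narrow thematic
    roles, verb- and noun-identity models); simulates multi-participant
    single-trial beta-map datasets on a voxel grid with planted signal
    populations; scores per-voxel generalization with a leave-one-run-out
    cross-validated, z-scored squared-difference diagonal contrast; performs
    group inference by within-run permutation, bootstrap aggregation and
    FDR-corrected cluster tests; and compares encoding models within regions of
    interest using leave-one-participant-out voxel selection and linear
    mixed-effects models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    RNifti,
    jsonlite,
    lme4,
    emmeans,
    stats,
    utils,
    tools,
    graphics
Suggests:
    car,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
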