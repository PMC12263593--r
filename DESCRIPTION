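Package: connectoprint
Title: Leverage-Score Fingerprinting of Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies individual-specific functional-connectome edge
    features by deterministic leverage-score selection and quantifies
    their similarity structure, their stability across age cohorts and
    brain parcellations, and their invariance to chronological age.
    Includes a seeded synthetic connectome-study generator with planted
    fingerprint and age-drift edges, so the full pipeline (connectome
    construction, feature selection, similarity nulls, cohort stability,
    cross-atlas overlap, age regression and cross-validated age
    prediction) can be exercised end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
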