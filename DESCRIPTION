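Package: promtriage
Title: Patient-Reported Outcome Triage for Total Hip Arthroplasty Follow-Up
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to build and evaluate a patient-reported outcome (PRO)
    triage rule that allocates total hip arthroplasty patients to a hospital
    or a video follow-up consultation. Implements scoring and direction
    recoding for the standard Dutch PROM set (NRS pain, EQ-5D-3L, EQ VAS,
    Oxford Hip Score, HOOS-PS), a six-stage clinimetric item-selection
    procedure (distribution, floor effect, responsiveness, PRO patient
    journey, correlation pruning, homogeneity via Cronbach alpha
    if-item-deleted), threshold-based cohort triage with allocation-rate
    comparison, baseline cohort comparison tables, and a latent-Gaussian
    ordinal cohort simulator for testing the whole pipeline without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
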