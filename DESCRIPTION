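Package: dietchoice
Title: Scoring and Inference for a Dietary Decision-Making Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores the shortened Three-Factor Eating Questionnaire
    (TFEQ-R18) onto 0-100 subscales with a disinhibited-eating composite,
    scores a two-phase dietary decision-making task (referent selection,
    trial-level health/taste difference scores, per-participant health and
    taste sensitivity coefficients, preference proportions, reaction-time
    outlier trimming), and reproduces the study-style inference: participant
    cleaning, covariate screening, standardized regressions of task outcomes
    on eating-behavior scores, trial-level reaction-time regressions, and
    moderation by cognitive restraint or disinhibited eating (median-split
    and continuous). Includes a synthetic-cohort generator with known ground
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
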