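Package: emaflow
Title: Headless Engine for Ecological Momentary Assessment and
    Intervention Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, headless engine for designing and exercising
    mobile e-coaching studies (ecological momentary assessment and
    just-in-time adaptive interventions). Provides a declarative study
    definition schema with a structural validator, a per-participant
    module lifecycle state machine driven by opening and closing timing
    rules, a notification dispatch planner with reminder and closing-lead
    semantics, a calculated-variables expression language with cohort
    aggregation functions, daily aggregation of wearable biomarker
    streams (steps, pulse rate, sleep episodes), and a seeded
    virtual-participant simulator with adherence reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
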