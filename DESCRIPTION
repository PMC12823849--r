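Package: bttcea
Title: Cost-Effectiveness of Bridge-to-Transplant Temporary Mechanical
    Circulatory Support
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A two-arm Markov cohort model comparing bridge-to-transplant
    temporary mechanical circulatory support (BTT-tMCS) against non-bridged
    heart transplantation from the healthcare payer perspective. Includes a
    synthetic patient-cohort generator, propensity-score matching with
    balance diagnostics, EQ-5D-5L utility indexing through pluggable value
    sets, moment-matched beta/gamma parameter distributions, half-cycle
    corrected discounted cost and QALY accumulation, incremental
    cost-effectiveness and net monetary benefit outputs, and deterministic
    (tornado) plus probabilistic (CEAC) sensitivity analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
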