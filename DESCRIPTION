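Package: closecon
Title: Health-Economic Decision Model for Femoral Venous Closure Devices
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic cost-utility decision model quantifying the
    effect of suture-based femoral venous closure devices, German day-case
    (section 115e SGB V) DRG billing, and early discharge from the
    post-anesthesia care unit (PACU) on contribution margin, case
    throughput, staff load and quality-adjusted life years (QALYs) after
    catheter ablation. Includes one-way and break-even sensitivity
    analysis, probabilistic sensitivity analysis, and a seeded
    patient-level PACU microsimulation that cross-validates the
    deterministic layer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
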