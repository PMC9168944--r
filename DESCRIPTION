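Package: rehabcompass
Title: Scoring and Compass Visualization of Stroke Patient-Reported Outcomes
Version: 0.1.0
Authors@R: person("Rehabcompass", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scores six stroke patient-reported outcome measures (SIS 3.0 with
    additional questions, HADS, FAS, smRSq, EQ-5D-3L, EAT-10) at item level,
    normalizes every functional domain onto a common 0-100 best-health scale,
    assembles the seven-area color-banded rehab compass graph with a
    minimum-value inner marker, compares snapshots across follow-up
    time points, and summarizes unmet rehabilitation needs (median, IQR,
    impairment frequency) at cohort level. Includes a seeded synthetic-cohort
    generator, SVG/PNG rendering, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
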