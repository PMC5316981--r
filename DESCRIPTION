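Package: colomotor
Title: Detection and Classification of Colonic Motor Patterns from
    High-Resolution Manometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated detection, classification and quantification of
    intraluminal pressure patterns in high-resolution colonic manometry
    (HRCM) recordings: simultaneous pressure waves, antegrade and
    retrograde propagating waves, high-amplitude propagating waves,
    isolated pressure transients, rhythmic haustral-boundary activity,
    intrahaustral segmentation and synchronized haustral pressure waves.
    Includes screening of abdominal-pressure artifacts (coughs, body
    shifts, talking, drinking) using annotation logs and the internal
    anal sphincter pressurization-versus-relaxation rule, a
    ground-truthed synthetic recording generator for validating every
    stage, and per-session and cohort summary statistics (paired and
    independent t tests, exact McNemar, Fisher exact, baseline-adjusted
    linear and logistic comparisons).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
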