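Package: glycalert
Title: Rule-Based HbA1c Monitoring and Alerting for Inpatient Mental Health
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An event-driven clinical decision support pipeline for
    dysglycaemia and diabetes monitoring on psychiatric wards. Replays a
    time-ordered log of admissions, discharges and glycated haemoglobin
    (HbA1c) laboratory reports, classifies results against configurable
    NICE-style diagnostic thresholds, schedules screening reminders for
    untested inpatients (first at four days post-admission, weekly
    thereafter), and emits deduplicated alerts carrying guideline-based
    recommendations. Includes a seeded synthetic ward-cohort generator,
    an independent brute-force replay oracle, a conformance report in
    the style of an in-silico validation audit, plain-text and HTML
    alert rendering, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
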