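Package: icualarms
Title: Cross-Sensor Alarm Rules for ICU Vital-Sign Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A rule engine for multi-parameter bedside-monitor alarms that
    correlate information across sensors to raise positive predictive value.
    Provides S4 containers for multichannel vital-sign time series, sustained
    absolute-threshold and relative-change triggers with conjunction
    ("ALL-of") scenario semantics, the five built-in haemodynamic alarm
    scenarios (SVT+BP, Vtach+BP, LV shock, tamponade, hypovolemia), a seeded
    generator of synthetic ICU records with labelled clinical episodes and
    sensor artifacts (damped arterial line, CVP infusion spikes, leveling
    errors, motion, disconnects), and an evaluation layer that classifies
    alarm events (true positive, false positive artifact, false positive
    insufficient definition, false negatives) and computes per-scenario
    positive predictive values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'icualarms-package.R'
    'channels.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'trace.R'
    'record.R'
    'triggers.R'
    'scenarios.R'
    'engine.R'
    'simulate.R'
    'evaluate.R'
    'pipeline.R'
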