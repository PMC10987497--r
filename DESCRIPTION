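Package: ThermoClock
Title: Temperature Encoding in the Drosophila Circadian Circuit
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative pipeline for studying how ambient temperature is
    encoded by the Drosophila circadian neuronal circuit. Scores sleep and
    locomotor activity from 10-second video epochs, computes
    temperature-response behavioral indices (evening-peak advance, offset
    delay, night-time and evening sleep reduction), quantifies GCaMP calcium
    traces (dF/F0, step-response fold change, saturation, circadian gating),
    reconstructs a 24-hour diurnal calcium curve from phase-shifted
    ratiometric recording groups, ranks connectome synaptic partners with
    Sankey export, and ships a synthetic-data generator with planted,
    recoverable parameters so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'synth-config.R'
    'synth-activity.R'
    'synth-calcium.R'
    'synth-connectome.R'
    'calcium.R'
    'circadian.R'
    'sleep.R'
    'indices.R'
    'stats.R'
    'connectome.R'
    'io.R'
    'accessors.R'
    'show-methods.R'
    'report.R'
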