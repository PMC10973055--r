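Package: splitaudit
Title: Auditing Train/Validation/Test Splits of Surgical Workflow Annotations
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing dataset partitions used in surgical phase and
    instrument recognition. Parses frame-wise phase and binary instrument
    annotations (Cholec80-style TSV dialects), derives workflow attributes
    (phase occurrence, phase transitions with start/end sentinels,
    surgery durations, individual instrument occurrence, exact-set instrument
    co-occurrence combinations, idle frames), aggregates them per
    train/validation/test set, flags attributes that are unrepresented in any
    set, supports pure re-assignment of surgeries between sets and a greedy
    split improver, simulates annotation datasets with the statistical
    structure of surgical workflows, and renders static phase, instrument and
    supplementary views.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    igraph,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
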