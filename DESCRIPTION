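Package: psgkit
Title: Stage-Time-Aware Analysis of Sleep EEG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Import polysomnography recordings (EDF, BrainVision) and
    sleep-stage notations in several scoring-software dialects, embed the
    stages as signal markers, and restrict analyses jointly by sleep stage
    and chronological time. Provides band-specific spectral amplitude
    estimation, filter-Hilbert amplitude envelopes, Morlet time-frequency
    decomposition, amplitude-threshold sleep spindle detection, and
    cluster-based permutation comparison of groups over scalp topography,
    plus a ground-truthed synthetic polysomnography generator for
    validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
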