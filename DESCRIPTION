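Package: fesgait
Title: Adaptive Functional Electrical Stimulation for Dropfoot Gait in
    Closed-Loop Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Cycle-to-cycle fuzzy-logic control of stimulation intensity
    and speed-adaptive stimulation timing for functional electrical
    stimulation (FES) assisted dropfoot gait, together with the marker and
    footswitch signal processing it depends on and a synthetic
    hemiparetic treadmill-walking plant. Simulates and summarises the
    four study conditions (no stimulation, heel-off triggered, speed
    adaptive, and intensity- and duration-adaptive stimulation) at
    multiple walking speeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
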