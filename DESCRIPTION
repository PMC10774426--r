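Package: moltdive
Title: Dive, Surface-Swim and Ingestion-Event Detection from Multi-Sensor
    Biologging Records of Molting Seals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and classification of at-sea behavior (dives, surface
    swimming, mud-pool wallows) from 10-second time-depth-recorder records,
    and detection, quantification and water-versus-prey classification of
    ingestion events from stomach-temperature-pill records. Includes
    zero-offset depth correction, diel light-level adjustment by seasonal
    decomposition, rolling-window outlier filtering, Kendall-tau/Theil-Sen
    sensor-drift assessment, pill-loss and hyperthermia detection,
    behavioral-context assignment with a solar day/night classifier,
    per-individual and cohort summaries with a PCA swimming score, and a
    ground-truth-labelled multi-sensor simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
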