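Package: pulseid
Title: Tracking and Electric-Image Analysis of Pulse-Type Weakly Electric Fish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for multichannel electrode recordings of pulse-type
    weakly electric fish. Simulates dipole fields to evaluate electrode
    arrays, detects and normalizes electric organ discharges (EODs),
    assigns each EOD to an individual by regressing fish position from the
    multichannel waveform with a random-forest model, reconstructs closed
    3D fish surfaces from tracked midline skeletons, computes active and
    passive electric images with a boundary element method, and summarises
    dyadic agonistic encounters (dominance, first-detection analysis).
    Ships a deterministic synthetic-data generator so the whole pipeline is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ranger,
    nnet,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
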