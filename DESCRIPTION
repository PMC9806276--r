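Package: spotspray
Title: Machine-Vision Target Spraying: Weed Detection, Valve Decisions, and
    Field-Pass Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Toolkit for camera-guided spot spraying of weeds with a boom
    sprayer whose nozzles are switched individually by solenoid valves.
    Implements pixel-to-ground calibration and the real-time grille-width
    constraint, the grille decision algorithm that turns per-frame detection
    boxes into a valve open/close bit vector, a checksummed serial frame
    protocol with valve rate limiting, a lightweight single-stage weed
    detector (MobileNetv3-Small backbone with squeeze-and-excitation
    attention and a PANet neck) with toy-scale training and standard
    detection metrics (precision, recall, F1, average precision), spray
    trial accounting (effective recognition rate, relative and absolute hit
    rates), and a stochastic field-pass simulator that generates synthetic
    weed scenes, renders annotated frames, and reproduces the trial-table
    bookkeeping in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    xml2,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
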