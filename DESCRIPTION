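Package: vtloop
Title: Closed-Loop All-Optical Ventricular Tachycardia Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic in-silico re-creation of a closed-loop all-optical
    cardiac mapping platform. A virtual heart renders voltage-sensitive-dye
    fluorescence frames from an activation-time (eikonal-style) wave model with
    channelrhodopsin-like response to patterned light; a discrete-event engine
    runs the platform's two asynchronous tasks (an imaging loop with
    single-slot latest-frame hand-off, and a real-time analysis loop that
    detects depolarization from a shift-register buffer of ROI means) together
    with the three-phase stimulation protocol that closes the loop and mimics
    a re-entrant ventricular tachycardia. Offline tools extract ROI traces and
    dF/F, re-detect events as an independent oracle, compute cycle-length and
    frame-loss statistics, build activation maps, and recover conduction
    velocity. Frames persist as uncompressed 16-bit grayscale TIFF stacks with
    microsecond-timestamp filenames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
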