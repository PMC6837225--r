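Package: hrvkinetics
Title: Heart-Rate Variability and Exercise HR Kinetics from RR-Interval Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for beat-to-beat RR-interval recordings around
    exercise sessions: artifact detection and correction by percentage-jump
    rules, selection of the most stable 256-beat segment, time-domain
    (SDNN, RMSSD, pNN50) and frequency-domain (LF/HF band powers, normalized
    units) heart-rate variability, monoexponential fitting of heart-rate
    on- and off-transients (baseline, amplitude, time constant, delay, fit
    diagnostics), and heart-rate-recovery delta profiles at 30-s landmarks.
    Includes a synthetic RR-series generator that emulates full training
    sessions (rest, warm-up, continuous or interval exercise, recovery) with
    known ground truth, and an orchestrator that produces tidy per-recording
    and per-cohort summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
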