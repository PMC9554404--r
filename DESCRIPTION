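Package: wristpa
Title: Raw Wrist Accelerometry Processing and Physical Activity Guideline Adherence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Processes raw tri-axial wrist acceleration recordings (nominally
    50 Hz, +/-8 g) into 5-second ENMO epochs and daily physical activity
    summaries, and classifies adherence to four activity criteria: the 2010
    WHO guideline (>=30 min/day of moderate-to-vigorous physical activity in
    bouts of >=10 min), the 2020 WHO guideline (>=30 min/day MVPA of any bout
    length), and daily step targets of 7,500 and 10,000 steps. Includes
    sphere-fit autocalibration against local gravity, non-wear and sleep
    period detection, windowed-peak-detection step counting with cadence
    metrics, MX (most-active-minutes) metrics, and a synthetic raw-signal
    generator with exact ground truth so that every processing stage can be
    validated without access to patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
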