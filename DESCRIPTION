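Package: edacross
Title: Electrodermal Activity Engagement Analysis via Moving-Average Crossovers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing single-channel electrodermal activity (EDA)
    recordings from media-viewing sessions: cleaning and min-max normalization,
    baseline-corrected session metrics (mean EDA, best-fit trend slope),
    stimulus-response latency estimation, classification of EDA profiles into
    five trend/peak morphologies, and detection of engagement and disengagement
    onsets with a dual-window simple-moving-average crossover (the analogue of
    the golden/death crossover of financial time-series analysis), including
    triage of false-positive and short-lived crossings. A seeded synthetic-EDA
    simulator (piecewise-linear tonic level, bi-exponential skin conductance
    responses, Gaussian measurement noise, ground-truth engagement track)
    supports end-to-end validation without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
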