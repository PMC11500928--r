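Package: blindcut
Title: Blinded Segmentation, Randomization and Scoring of Video and Image Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless workflow for unbiased scoring of video and image data.
    Source media are cut into labeled rectangular segments, the pooled
    segments are shuffled with an explicit Fisher-Yates algorithm and
    presented for scoring under anonymous blinded identifiers, and the
    completed scores are unblinded into a results table (CSV and XLSX)
    joining segment labels, source files and per-stage notes. Sessions are
    persisted as JSON and can be paused and resumed without disturbing the
    randomized order. Includes a synthetic multi-well-plate fixture
    generator (moving-blob wells with known activity levels) and a simple
    frame-differencing activity scorer so the full pipeline can be
    exercised end-to-end without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jpeg,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    zip
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
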