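Package: shimpr
Title: Analysis of Suppression Head Impulse Paradigm (SHIMP) Video Head
    Impulse Test Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies anticompensatory saccades in suppression
    head impulse paradigm (SHIMP) video head impulse test (vHIT) recordings.
    Implements topographic peak detection on head and eye angular-velocity
    traces (local maxima, prominence, width at half prominence), a dual-pass
    eye analysis that separates the vestibulo-ocular reflex response from the
    SHIMP refixation saccade, a width-based early-saccade time period (ESTP)
    classifier that is robust to head-impulse overshoot, per-test and
    per-protocol summary statistics, a ground-truth simulator of
    impulse/response velocity traces, readers and writers for an open CSV/XML
    trace dialect and a JSON results schema, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
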