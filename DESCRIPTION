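Package: cavitrace
Title: Xylem Cavitation Resistance from Acoustic Emission Rates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for estimating xylem cavitation resistance of woody plants
    from ultrasonic acoustic emission (AE) monitoring during branch
    dehydration. Computes time-dependent AE activity (hits per minute) from
    hit logs, locates the activity peak with Savitzky-Golay smoothing, and
    interpolates the water potential at maximum AE activity (Pmaxrate).
    Also fits reparameterized Weibull hydraulic vulnerability curves to
    percent-loss-of-conductivity data with bootstrap confidence intervals,
    compares acoustic and hydraulic vulnerability estimates across species
    by least-squares regression with influence diagnostics, and simulates
    dehydration experiments with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
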