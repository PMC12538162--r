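Package: optopulse
Title: Virtual Pulse-Train Generator and Signal Metrology for Optogenetic Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pure-software emulation of a microcontroller-based laser
    stimulation controller for optogenetics, together with the analysis
    toolkit used to characterise it. Synthesises square, sinusoidal and
    half-sinusoidal pulse trains for up to four laser channels with burst,
    duty-cycle, attenuation-ramp and delay parameters and 12-bit DAC
    quantisation; emulates the trigger/priming/debounce state machine with
    mock (mask-only) trials and mask mirroring; speaks a line-delimited JSON
    control protocol; fits linear laser power calibrations; and extracts
    timing-validation statistics (pulse and interpulse durations, trigger
    lag, intersignal offset, frequency estimates, instantaneous phase and
    circular phase-offset statistics) from uniformly sampled traces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
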