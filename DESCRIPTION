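Package: tonomapr
Title: Tonotopic Map Analysis of Auditory Cortex Multiunit Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs frequency-intensity receptive fields from multiunit
    spike recordings of the rat primary auditory cortex (AI) and extracts the
    standard map statistics: characteristic frequency (CF), intensity
    threshold, bandwidth 10 dB above threshold (BW10), onset latency,
    receptive-field irregularity index and tuning-curve shape class.
    Assembles per-site metrics into cortical maps, delineates AI by response
    criteria, renders Voronoi tessellation maps, and quantifies map order with
    a normalized tonotopic index. Includes a Poisson spike-train simulator
    that generates ground-truthed control and VPA-like cohorts on an 8 x 8
    electrode array so that every estimator can be validated by parameter
    recovery, plus per-animal summaries and two-group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    readr,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
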