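Package: fpvs
Title: Frequency-Tagged EEG Analysis of Fast Periodic Visual Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing fast periodic visual
    stimulation (FPVS) experiments that embed a periodic expression
    regularity in a rapid serial stream of face images. Builds
    frame-accurate stimulus session plans with target scheduling,
    forward-simulates multichannel EEG epochs with steady-state responses
    at the stimulation and regularity frequencies, screens artifacts with
    z-score channel and epoch criteria (including spherical-spline
    interpolation, kurtosis and spectral-deviation screens), derives
    per-condition narrowband spatial filters by generalized
    eigendecomposition (RESS), extracts Fourier phases on a fixed 0.1 Hz
    grid, computes the pairwise cosine-similarity phase-clustering index
    alongside inter-trial coherence, and contrasts conditions with a
    Bayesian multilevel model summarised by posterior means,
    highest-density intervals and evidence ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    rjags,
    coda
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
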