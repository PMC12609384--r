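Package: gazeog
Title: Gaze-Direction Estimation from Electro-Oculography with
    Proprioceptive Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for validating electro-oculography (EOG) based
    horizontal and vertical gaze-direction estimation against a
    camera-based eye tracker and against the instructed fixation
    trajectory of a tactile (proprioceptive) calibration task.
    Provides construction of piecewise-constant instructed gaze
    trajectories, a synthetic trial and cohort generator with
    saccadic dynamics, drift, blink and spike artifacts and modality
    lags, the signal-conditioning chain (linear detrending, median
    filtering, Haar continuous-wavelet blink detection and removal,
    Hampel filtering, sliding-window dispersion, z-scoring,
    resampling), grand averaging, cosine similarity and normalized
    cross-correlation lag analysis, a Shapiro-gated paired test
    battery with Bonferroni correction and TOST equivalence testing
    with a standardized smallest effect size of interest, post hoc
    power for paired designs, and a shuffled-trajectory surrogate
    control for eyes-closed trials.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
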