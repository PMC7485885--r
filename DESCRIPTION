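Package: handwritr
Title: Handwriting Kinematics, Digital Features and Dysgraphia Subtyping
    from Pen-Tablet Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational analysis of handwriting acquisition
    recorded on pen tablets. Reads and segments timestamped pen-sample
    streams, harmonizes pressure scales across devices with a monotone
    polynomial response model, and extracts twelve static, kinematic,
    pressure and tilt features (spectral medians and bandwidths of speed,
    tremor and tilt series, in-air-time ratio, handwriting-density
    dispersion, pressure-change speeds, and spectral distances to per-grade
    reference writers). Provides age-normalized BHK scoring and dysgraphia
    diagnosis, developmental linear models with case-resampling bootstrap
    inference (BCa intervals, percentile p values), K-means subtyping with
    clustering-tendency (Hopkins), k-selection by index majority and
    bootstrap-Jaccard stability diagnostics, and a synthetic pen-trajectory
    and cohort simulator with planted developmental effects and subtype
    profiles so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
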