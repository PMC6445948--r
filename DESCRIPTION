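Package: ivmax
Title: Maximum Sliding Velocity of Actin Filaments in the In Vitro
    Motility Assay
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates the maximum sliding velocity of actin filaments in
    the in vitro motility assay (IVMA) from filament tip tracking data.
    Frame-to-frame velocity signals are reconstructed with a
    constant-velocity Kalman filter, partitioned into phases of
    homogeneous velocity by a split-and-merge procedure with sequential
    Welch t-tests, and summarised by a top-fraction phase-velocity
    statistic. Includes a seven-filter signal-reconstruction benchmark,
    readers for MTrackJ MDF and generic CSV tracking data, and synthetic
    track and fluorescence image-sequence generators with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
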