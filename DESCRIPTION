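Package: seqreach
Title: Kinematic Analysis of Sequential Reaching and Movement Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing 2-D sequential reaching movements: velocity
    profile computation and proximity-based segmentation of multi-target
    reach sequences, a per-transition movement-fusion index, sliding-window
    spatial-reorganization (radial distance) metrics, minimum-jerk via-point
    reference trajectories and smoothness scoring (velocity-profile MSE and
    spectral arc length), a closed-loop rank-based reward schedule, and
    participant-level bootstrap inference for trial-by-trial learning
    curves. Includes a synthetic trajectory generator with controllable
    fusion level, movement-time trends and corrective submovements, so the
    full pipeline is testable without experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
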