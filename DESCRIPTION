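Package: earmotion
Title: Activity Tracking from Ear- and Waist-Level Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying human activity recognition with tri-axial
    accelerometers worn at ear level (as in hearing aids) and at the waist.
    Provides a physics-based generator of labeled synthetic recordings for
    nine activities (standing, sitting, three lying postures, walking,
    jogging, falling, transitioning), per-sample extraction of a
    33-dimensional time-domain feature set (tilt angles, acceleration vector
    change, signal magnitude area, windowed moments and order statistics,
    and ActiGraph-style activity counts), bagged decision-tree
    classification with seeded determinism, confusion-matrix and
    feature-ablation evaluation harnesses, multi-sensor combination
    experiments, and step detection from the acceleration-vector-change
    signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
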