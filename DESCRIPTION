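Package: gaitarm
Title: Frontal-Plane Arm Kinematics and Ordinal Impairment Scoring from
    Marker-Less Gait Video Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing arm movement abnormality during walking from
    marker-less pose-estimation output. Reads per-frame landmark traces
    (shoulders, elbows, wrists, hips) in the standard pose-tool CSV dialect,
    trims each trial to the walking portion, median-filters landmark
    coordinates, computes frontal-plane elbow and shoulder angle series,
    reduces each trial to 24 distributional summary features, predicts
    ordinal clinical impairment scores (0-4, ICF qualifiers) with a random
    forest under nested cross-validation, and evaluates agreement with human
    assessors (accuracy, mean square error, score-difference tallies,
    quadratic weighted Cohen's kappa with bootstrap standard errors,
    prediction-bias t-tests, across-network ANOVA, and binary
    impaired/unimpaired contingency metrics). Includes a synthetic gait
    cohort generator so the full pipeline is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
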