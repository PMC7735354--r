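Package: flapglide
Title: At-Sea Behaviour, Dives and Foraging Niche from Seabird Biologgers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for combined GPS, tri-axial accelerometer and
    pressure loggers deployed on central-place foraging seabirds. Converts
    25 Hz acceleration into a per-second ethogram (flapping flight, soaring
    flight, rafting on water) via heave-axis spectral features and k-means,
    detects surface foraging from body pitch and dives from zero-offset
    corrected pressure, computes trip geometry (speed filtering, trip
    segmentation, haversine metrics, convex-polygon home range, trip-duration
    bimodality), grids standardized foraging effort for habitat matching, and
    quantifies sexual size dimorphism (Storer index) and isotopic niche width
    (standard ellipse areas, including a Bayesian version). Ships a synthetic
    biologger that emulates the sensor outputs with per-second ground truth,
    so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    geosphere,
    mclust,
    e1071,
    zoo,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
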