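Package: parkscape
Title: Plot-Scale Analysis of Park Landscapes and Health-Behavior Intensity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how urban-park landscape composition
    supports health-promoting behavior at the plot (30 m x 30 m) scale.
    Converts semantic-segmentation label maps into 11-feature landscape
    fraction profiles, scores SOPARC-style behavior observations into
    MET-weighted intensity indices (overall, exercise, leisure, social),
    screens features by Spearman correlation and variance inflation,
    fits multiple linear regression models linking landscape to intensity,
    and extrapolates fitted models over whole parks via a fishnet grid
    with Jenks natural-breaks classification. Includes observer-reliability
    metrics (intraclass correlation, percent agreement) and a seeded
    synthetic-data generator so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
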