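Package: swimtrackr
Title: Multi-Fish Swim Tracking, Kinematics and Segregation Statistics
Version: 0.1.0
Authors@R: person("swimtrackr", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies adult fish swim behaviour from overhead tank videos:
    colour-deconvolution greyscale conversion, median time-projection
    background subtraction, intermodes-threshold segmentation, multi-animal
    track linking with the Munkres (Hungarian) assignment algorithm,
    backbone skeletonisation with smoothing-spline curvature profiles, and
    per-fish kinematic summaries (instantaneous velocity and range of
    movement over the most-active frames). Also provides the organism-level
    statistics used alongside such screens: two-way ANOVA with Sidak
    adjustment, fish morphometric indices (BMI, Fulton's condition factor
    K) and Mendelian segregation chi-square tests. Ships a synthetic
    swimming-fish video generator with exact ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
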