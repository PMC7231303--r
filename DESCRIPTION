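Package: movecomp
Title: Compositional and Multivariate Pattern Analysis of 24-Hour Movement
    Behaviors
Version: 0.1.0
Authors@R:
    person("Movecomp", "Developers", email = "movecomp@example.org",
           role = c("aut", "cre"))
Description: Tools for relating accelerometer-assessed 24-hour movement
    behaviors (sleep, sedentary time, light and moderate-to-vigorous
    physical activity) to continuous health outcomes such as regional
    gray-matter volume.  Provides epoch-level accelerometer reduction
    (intensity classification, non-wear imputation, weekday/weekend
    weighting, validity filtering, a 33-band intensity spectrum),
    standard linear models with a weight-status moderation screen,
    compositional data analysis via isometric log-ratio pivot
    coordinates with isotemporal-substitution reallocation curves,
    partial least squares regression with Monte-Carlo cross-validation,
    target projection and selectivity ratios, and a synthetic-cohort
    generator emulating a pediatric overweight/obesity study design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
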