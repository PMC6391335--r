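Package: alcv
Title: Anterior Lens Capsule Vascularity Quantification and Gestational Age Prediction
Version: 0.1.0
Authors@R:
    person("ALCV", "Maintainers", email = "maintainers@alcv.dev", role = c("aut", "cre"))
Description: Semiautomated quantification of anterior lens capsule vascularity
    (ALCV) from retroillumination images of the neonatal eye, and prediction of
    gestational age from the resulting imaging biomarkers. Implements circular
    Hough pupil detection with weighted candidate voting and RGB/HSV boundary
    refinement, red/green contrast stretching and hysteresis vessel
    segmentation, skeleton-based branch morphometry with box-counting fractal
    tortuosity, a random-intercept mixed linear model for repeated sessions,
    multicollinearity (VIF) screening, Bland-Altman agreement analysis, and a
    Hittner grade lookup. Ships a fixed-coefficient gestational age predictor
    and a synthetic retroillumination scene generator with analytic ground
    truth so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    igraph,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    jpeg,
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
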