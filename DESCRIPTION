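Package: spareal
Title: Spatial Autocorrelation and Spatial Regression for Areal Health Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: District-level spatial analysis of health-indicator percentages on
    areal units: queen-contiguity spatial weights (with GAL serialization),
    global Moran's I with Monte-Carlo permutation inference, local Moran (LISA)
    with conditional permutation and HH/LL/HL/LH cluster classification,
    ordinary least squares with collinearity and Lagrange-multiplier spatial
    diagnostics, and maximum-likelihood spatial error and spatial lag models
    with likelihood-ratio, AIC and Breusch-Pagan model comparison. Includes a
    synthetic-data module that generates square-lattice geometries and
    district-style attribute tables under known spatial data-generating
    processes, and a pipeline driver that runs the full workflow from a config.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
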