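Package: flowstack
Title: Spatial Interaction Models and a Stacked Poisson Ensemble for
    Origin-Destination Flows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fits five classical spatial-interaction models (gravity,
    gravity with a distance cut-off, radiation, radiation with selection,
    and intervening opportunities) to origin-destination flow matrices by
    Poisson maximum likelihood, combines their predictions with a stacked
    Poisson generalised linear model, and compares all models by k-fold
    cross-validated Poisson deviance.  Includes a seeded synthetic-data
    generator producing census-like commuter counts or GPS-like normalised
    intensities, CSV/JSON readers and writers for locations, flows and
    fitted models, and a command-line interface covering the whole
    simulate-fit-stack-validate pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
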