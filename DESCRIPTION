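Package: petolv
Title: Cancer-Immune Lotka-Volterra Dynamics and Lifespan Scaling for
    Peto's Paradox
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a three-compartment Lotka-Volterra model of
    cancer cells, healthy cells and a declining immune-escape threshold
    over a species' lifespan; detects the immune-escape tipping time
    (the first crossing of the growing cancer population and the falling
    immune threshold) and converts it to a lifetime cancer incidence.
    Provides closed-form equilibria with eigenvalue stability
    classification, allometric power-law scaling of all model
    coefficients from lifespan, nondimensionalization onto the unit
    lifespan, species-ensemble construction, and numerical verification
    that lifespan-scaled ensembles share identical rescaled tipping
    times and hence identical cancer incidence (Peto's paradox).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
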