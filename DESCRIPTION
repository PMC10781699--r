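Package: aquarisk
Title: Heavy-Metal Pollution Indices and Probabilistic Human Health Risk
    for Water Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for assessing heavy-metal contamination of surface water
    and groundwater and the associated human health risk. Computes the heavy
    metal pollution index (HPI) and metal index (MI) with their standard
    classification scales, deterministic USEPA-style chronic daily intake,
    hazard quotient/index and carcinogenic risk for adult and child receptors
    through oral and dermal routes, and seeded Monte Carlo propagation of
    concentration uncertainty through the same equations. Includes simple
    hydrochemical classification (TDS by ion summation, ionic balance error,
    chloro-alkaline index, salinity and Sulin genetic typing) and a synthetic
    survey generator that emulates a desert-oasis water survey from published
    summary statistics via truncated-lognormal marginals and a Gaussian
    copula.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
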