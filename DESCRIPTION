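Package: weedclass
Title: Classifying Arable Farming Regimes from Weed Functional Traits
Version: 1.0.0
Authors@R: person("weedclass", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Organises archaeobotanical weed seed counts into per-sample
    functional-trait profiles, classifies them against two-group linear
    discriminant models of modern farming regimes (high- vs low-input
    cultivation; high vs low soil disturbance), and visualises discriminant
    scores as one-dimensional beeswarm plots. Ships a species-level trait
    database interface with a compact four-three species-code scheme,
    composite-taxon averaging, sample cleaning filters, a fully seeded
    synthetic data generator for end-to-end testing without external
    downloads, and a command-line pipeline with provenance manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    optparse
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
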