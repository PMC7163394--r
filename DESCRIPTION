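Package: caprifeed
Title: Phenotyping Feed Intake Patterns in Dairy Goats
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing individual feed intake patterns of
    dairy goats from automated trough-weight recordings. Raw 2-min trough
    weights are converted to monotone cumulative dry matter intake profiles
    scaled to body weight, summarized by an exponential intake model and by
    penalized piecewise-linear segmentation with slope clustering and
    first-meal detection, and condensed into eleven aggregate behavioural
    traits (early-intake fractions, intake-curve parameters, first-meal
    intake, fibre sorting index). A statistical layer provides nested
    fixed-effect ANOVA with custom error terms, within-period and
    between-period repeatability measures, between-period correlations and
    principal component analysis of the trait table. A seeded synthetic-herd
    generator with known latent traits makes the whole pipeline testable
    without access to animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
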