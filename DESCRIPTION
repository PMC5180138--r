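Package: corridorbees
Title: Bumblebee Transect-Survey Analysis for Infrastructure Corridor Habitats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing bumblebee transect surveys across habitat
    mosaics such as electricity transmission corridors, roadsides and
    semi-natural grasslands. Provides validated survey containers built on
    SummarizedExperiment, a seeded synthetic survey generator with known
    ground truth, additive alpha/beta/gamma diversity partitioning with
    exact individual-based (hypergeometric) rarefaction, plant-pollinator
    visitation matrices with dependency and species-strength tables,
    Gaussian linear mixed models with nested random effects and
    level-based denominator degrees of freedom, and simulation-based power
    estimation for percentage differences in expected response.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    nlme,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
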