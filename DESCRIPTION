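Package: riverscape
Title: Reach-Scale Stream Networks and Presence-Background Habitat Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts attributed, reach-scale stream networks from digital
    elevation models (depression filling, D8 flow routing, flow accumulation,
    channel delineation, Strahler ordering, fixed-grain reach splitting),
    attaches topographic and upstream-catchment environmental predictors to
    every reach, fits presence-background maximum-entropy habitat models with
    L1-regularized feature expansions, evaluates candidate models by partial
    ROC, omission rate and AICc, and transfers, binarizes and overlays
    suitability across networks to quantify habitat overlap between species.
    Includes seeded synthetic terrain and virtual-species generators so the
    whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
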