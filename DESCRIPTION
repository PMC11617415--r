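Package: fortisim
Title: Simulation of Calcium Fortification of Wheat Flour from Dietary Recall Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates usual (long-run) calcium intake distributions from one or
    two 24-hour dietary recalls per person using a measurement-error model
    (Box-Cox transform, within- and between-person variance components,
    shrinkage of person means and Gauss-Hermite back-transformation), and
    simulates wheat-flour calcium fortification scenarios. Consumed foods are
    decomposed into white-wheat-flour grams, calcium is added at configurable
    mg per 100 g of flour, and the prevalence of intake below the estimated
    average requirement (EAR) and above the tolerable upper intake level (UL)
    is reported per age-sex group under complex-survey weighting. A seeded
    synthetic-survey generator with latent-truth oracles makes every stage
    testable without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
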