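Package: ltrepop
Title: Stage-Structured Matrix Population Models and Life Table Response
    Experiments for Designed Demography Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds three-stage annual projection matrices (seed,
    cotyledonous, flowering) from individual-level census data of designed
    field experiments, computes population growth rates (lambda), stable
    stage distributions, reproductive values, sensitivities and
    elasticities, and decomposes treatment effects on lambda with a two-way
    fixed-effect life table response experiment (LTRE). Includes
    designed-experiment statistics on vital rates (two-way ANOVA with a
    configurable error term, MANOVA, Tukey post hoc comparisons), a
    synthetic census generator emulating a biotype-by-selection common
    garden design, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
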