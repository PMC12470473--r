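Package: aedespread
Title: Municipal-Scale Analysis of Invasive Aedes Detections from Field and
    Citizen-Science Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the municipal-scale spread of invasive Aedes
    mosquitoes detected by two complementary surveillance strategies:
    professional field sampling and citizen-science reporting. Provides a
    validated data model for municipality registries and per-species
    first-detection tables, five-category attribution of first detections,
    annual and cumulative spread summaries, a province-stratified permutation
    test relating colonisation to population density, great-circle
    nearest-previous-positive detection distances with strategy comparison
    (t-test, two-way ANOVA with Tukey contrasts), and a stochastic
    invasion-plus-surveillance simulator with known ground truth for
    validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere
Config/testthat/edition: 3
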