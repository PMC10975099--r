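Package: ddiconcord
Title: Concordance Analysis of Drug-Drug Interaction Severity Ratings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring agreement between electronic drug-interaction
    checkers. Harmonizes checker-specific severity labels onto a unified 0-4
    interaction-strength scale, enumerates drug pairs under ATC Level-2
    category structure, stratifies two-checker agreement by strength-code
    difference, and computes Fleiss' kappa (overall and per category pair)
    with Landis-Koch agreement bands. Includes a seeded synthetic-data
    generator for two-rater severity datasets, deterministic worked-example
    fixtures, tidy accessors for all result objects, ggplot2 visualisations
    of agreement distributions and kappa heatmaps, and plain-text readers and
    writers for drug catalogs, ratings, and report bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
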