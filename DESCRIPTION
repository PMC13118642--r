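Package: nlcoptim
Title: Design, Optimization and Characterization of Lipid Nanoparticle
    Formulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the statistical workflow behind nanostructured
    lipid carrier (NLC) formulation development: rotatable central
    composite designs, polynomial response-surface fitting with
    lack-of-fit diagnostics, Derringer-Suich desirability optimization
    across multiple responses, formulation characterization arithmetic
    (entrapment efficiency, drug loading, DSC endotherm integration,
    crystallinity index), cumulative-release processing for
    fixed-volume-replacement dissolution sampling, and non-compartmental
    pharmacokinetic summaries. Includes synthetic-data generators that
    emulate replicated designed experiments, biphasic release curves and
    one-compartment oral-absorption profiles, plus a packaged 13-run
    case study.
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
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
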