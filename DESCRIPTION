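Package: cerebroflow
Title: Hematocrit-Aware Hierarchical Model of Cerebral Blood Flow in Preterm Infants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes cerebral blood flow (CBF) in the immature brain from a
    19-level hierarchical cerebrovascular model with a germinal-matrix capillary
    compartment. Apparent blood viscosity in arteries, arterioles and veins
    follows the diameter- and hematocrit-dependent in-vivo viscosity law
    (Fahraeus-Lindqvist effect); capillary resistance follows a two-phase
    single-file red-blood-cell flow model driven by the tube hematocrit.
    Includes a cohort-comparison pipeline (measured versus fixed 45% hematocrit,
    Wilcoxon rank-sum and Fisher exact tests) and a synthetic-cohort generator
    emulating routine neonatal monitoring records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
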