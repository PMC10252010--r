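Package: zoometry
Title: Zoometric Characterization of Andean Creole Cattle Biotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phenotypic characterization of cattle biotypes from linear body
    measurements. Provides a 17-trait bio-morphometric measurement schema with
    CSV interchange and plausibility screening, the ten classical zoometric
    indices (cephalic, thoracic, body, lateral body, anamorphosis, pelvic,
    dactyl-thoracic, dactyl-costal, transverse and longitudinal pelvic),
    rule-based classification of productive aptitude (dairy, beef,
    dual-purpose), descriptive summaries (mean, SEM, CV), unbalanced two-way
    analysis of variance with Tukey-Kramer pairwise comparisons and compact
    letter displays, Pearson correlation matrices with significance, and a
    synthetic-herd generator with a nearest-correlation (alternating
    projections) repair, calibrated to a reference population of 95 Andean
    Creole cattle in three biotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    Matrix,
    withr,
    yaml
Config/testthat/edition: 3
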