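Package: milkosm
Title: Osmolality Prediction and Quality Control for Target-Fortified Breast Milk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the final osmolality of fortified breast milk feeds for
    preterm infant nutrition. Calibrates per-additive linear osmolality
    coefficients from titration series, estimates per-dose human milk
    fortifier offsets, predicts feed osmolality for arbitrary fortification
    recipes in linear or mechanistic (osmole-bookkeeping) mode, computes
    target-fortification supplement doses against a macronutrient target
    profile, flags feeds that exceed the 450 mOsm/kg enteral safety limit or
    deviate from prediction (suspected preparation errors), and adjusts for
    cold-storage carbohydrate breakdown. Includes seeded synthetic-data
    generators for titrations, fortifier pairing experiments, storage series
    and clinical cohorts, plus CSV/JSON interfaces and a subcommand
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
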