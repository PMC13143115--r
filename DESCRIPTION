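Package: menutargets
Title: Menu Nutrition Completion and Adherence to UK Reduction Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for auditing restaurant menu nutrition data
    against the UK Government's voluntary sugar, salt, and calorie reduction
    targets. Completes missing nutrient fields with deterministic unit and
    basis conversion formulas (kJ/kcal, salt/sodium, per-100g/per-serving
    scaling, subcategory-mean serving-size imputation), assigns menu items
    to target categories under the sugar-before-calorie and OOH-before-
    retailer salt hierarchies (including sharing-pizza serving conventions),
    evaluates boundary-inclusive adherence on the correct nutrient basis,
    summarises nutrient content on three serving bases, and re-runs the
    analysis under limited-time-offer exclusion and quartile serving-size
    imputation sensitivity specifications. Ships a seeded synthetic menu
    corpus generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
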