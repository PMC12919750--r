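Package: nutrikiosk
Title: Rule-Based Meal Planning and Neural Triage for Diabetes Nutrition Kiosks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of an offline nutritional-recommendation kiosk
    for diabetes self-management. Provides a regional food-composition database
    backed by SQLite with diabetes-suitability and food-exchange queries,
    Harris-Benedict energy-requirement and macronutrient calculations, a
    synthetic diabetic-cohort simulator with stratified sampling and
    physiological consistency filters, a three-class multilayer-perceptron
    plan-triage classifier with a fixed-rule baseline, a deterministic greedy
    meal-plan composer under calorie, per-meal carbohydrate and food-group
    constraints, and the evaluation statistics used to audit such systems
    (per-class and averaged classification metrics, Wilson score intervals,
    System Usability Scale scoring, and a concurrent-load harness).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    jsonlite,
    stats,
    utils,
    graphics,
    parallel
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
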