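Package: nutricopd
Title: Rule-Based Nutritional Assessment and Recommendations for Patients with COPD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, explainable clinical rule engine for the
    nutritional management of patients with chronic obstructive pulmonary
    disease (COPD). Classifies patients by anthropometric phenotype (WHO BMI
    categories), COPD stage (FEV1 cutoffs), nutritional risk index (NRI),
    sarcopenia (hand grip, bioimpedance-derived appendicular skeletal muscle
    mass, gait speed) and cachexia (inflammatory and biochemical criteria),
    then derives a fourteen-item tailored nutritional recommendation (basal
    metabolic rate via Harris-Benedict or Mifflin-St Jeor, stage-corrected
    energy requirement, macronutrient shares and grams, micronutrient caps,
    supplementation flags, meal frequency). Every emitted value carries a rule
    trace distinguishing guideline-sourced constants from implementation
    assumptions. Includes a synthetic-cohort generator that inverts every
    published cutoff for boundary and lattice testing, CSV/JSON patient I/O,
    report writers, an RDF Turtle export using the copd: vocabulary, and
    agreement-score summaries for expert validation panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
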