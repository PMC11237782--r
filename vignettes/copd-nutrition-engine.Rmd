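---
title: "The COPD nutrition rule engine: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The COPD nutrition rule engine: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutricopd)
```

## Scope and model

`nutricopd` is a deterministic clinical rule engine for the nutritional
management of patients with chronic obstructive pulmonary disease (COPD).
From one tabular record per patient — demographics, anthropometrics,
spirometry, functional tests, bioimpedance, biochemistry, an optional blood
gas and two comorbidity flags — it infers five classifications and derives a
fourteen-item nutritional recommendation. Everything is rule-based: there is
no fitting, no randomness in the inference path, and every emitted value is
backed by an auditable rule with a provenance flag.

The classification layer computes:

* **Anthropometric phenotype** from BMI, using the WHO categories
  (underweight < 18.5, normal weight 18.5–25, overweight 25–30, obesity
  degrees I/II/III at 30/35/40 kg/m²).
* **COPD stage** from FEV1 % of predicted (I ≥ 80, II 50–80, III 30–50,
  IV < 30). Diagnosis itself (FEV1/FVC gating) is assumed done upstream.
* **Nutritional risk index**,
  $NRI = 1.519 \times \text{albumin (g/L)} + 41.7 \times
  \text{current/usual weight}$, classified as absence (> 100), mild
  (97.5–100), moderate (83.5–97.5) or severe (< 83.5) risk.
* **Sarcopenia** by the EWGSOP2-style operational ladder. Criterion 1 is low
  strength (grip < 27 kg male / < 16 kg female); criterion 2 low muscle
  quantity, assessed on the appendicular skeletal muscle mass estimated from
  bioimpedance with the Sergi equation
  $ASMM = -3.964 + 0.227\,RI + 0.095\,w + 1.384\,\text{male} +
  0.064\,X_c$, where $RI = \text{height(cm)}^2 / R$; criterion 3 poor
  performance (gait speed ≤ 0.8 m/s). Criterion 1 alone gives *probable*,
  1+2 *diagnosed*, all three *severe* sarcopenia.
* **Cachexia** as a particular case of sarcopenia: any sarcopenia level plus
  CRP > 10 mg/L, transferrin < 150 mg/dL and albumin < 3.5 g/dL.

The recommendation layer selects the basal metabolic rate equation by
phenotype (Harris–Benedict for underweight/normal weight, Mifflin–St Jeor
for overweight/obese), multiplies the rounded BMR by a correction factor
(1.5 for stages I/II, 1.8 for stages III/IV, and always 1.8 under cachexia),
and assigns protein, carbohydrate, fat, sugar, saturated fat, cholesterol,
fiber, sodium, calcium, meal frequency and two supplementation flags.

## The rule table

Every constant lives in one editable YAML table
(`system.file("extdata", "nutrient_rules.yaml", package = "nutricopd")`),
loaded by `nutrition_rules()` and validated for completeness at load time.
Each rule carries `provenance: guideline` (the constant comes from the
clinical rule base and its cited guidelines) or `provenance: assumption`
(the rule base fixed only a direction and this package chose a conventional
magnitude). The distinction surfaces in every report and in `rule_trace()`,
so a clinician reviewing an output can immediately see which numbers are
negotiable.

The assumption-flagged values, and why they were chosen once and not
revisited:

* **Sarcopenic (non-cachectic) protein multiplier, 1.5 g/kg.** The rule base
  raises protein for sarcopenic phenotypes without printing the factor;
  1.5 g/kg is the usual clinical target for muscle-wasted older adults,
  between the 1.2 g/kg default and the cachectic 25% energy share.
* **Obese protein basis, ideal weight at BMI 25 kg/m².** Dosing per measured
  weight would overfeed protein in obesity; the upper bound of the normal
  BMI band is the conventional ideal-weight anchor.
* **Hypercapnia carbohydrate shift, 5 percentage points.** Under
  pCO2 > 50 mm Hg the rule base shifts energy from carbohydrate to fat
  (lipid oxidation produces less CO2 per kcal); the direction is stated, the
  magnitude is not. One band width (45–50 → 40–45%) keeps the band structure
  intact.
* **Fiber 15–25 g/day** (below the Italian LARN reference, sparing the early
  satiety these patients report) and **calcium 1200 mg/day** (above the LARN
  reference, against osteoporosis): both directions are stated by the rule
  base relative to LARN; the magnitudes are conventional.
* **Meals per day, 5.** "Small and frequent" operationalized as five.
* **Absent pCO2 is treated as normocapnic** (blood gas is not always
  acquired), and **absent usual weight defaults to the current weight**
  (neutral NRI weight ratio of 1).

Two interpretation decisions worth recording: the biochemical cutoffs are
read as C-reactive protein in mg/L (> 10) and serum transferrin in mg/dL
(< 150) — the only clinical quantities for which those cutoffs are standard
— and criterion 2's two sub-conditions (absolute ASMM; ASMM/height²) are
combined with OR, the usual "either indicates low quantity" reading. The
supplementation rule for lean phenotypes is applied as *sarcopenic*
underweight or normal-weight patients receiving both BCAA and energy-protein
supplements; non-sarcopenic lean patients receive neither.

## Numerical choices

* **Rounding is half away from zero** (`round_half_up()`), the common
  behaviour of rule-language `round` built-ins, applied first to the BMR and
  then again to the corrected product — the engine reproduces the chained
  rule pipeline literally rather than multiplying at full precision.
  Grams are reported to 0.1 g; shares keep full precision internally.
* **Interval endpoints are half-open `[lo, hi)`** for BMI and FEV1, so the
  category partition is total with no gap at, say, BMI 24.95. The NRI bands
  follow their stated closures (absence strictly above 100, mild inclusive
  of both 97.5 and 100).
* **BMI ≥ 40 is classified as obesity degree III but routed through the
  degree-II rule branch** with a warning: the nutrient rule base defines
  five phenotypes, and the degree-II branch (Mifflin, ideal-weight protein)
  is the clinically conservative continuation.
* **Share feasibility**: fat is the residual of the share identity
  `protein + carb + fat = 100` at both ends of the carbohydrate band; a
  protein share large enough to drive the minimum fat share negative raises
  an error naming the conflicting rules rather than emitting an impossible
  diet.
* The synthetic boundary generator lands engineered quantities (BMI, NRI,
  ASMM) *exactly* on a cutoff by inverting the corresponding equation and
  then nudging the free input by one part in 2^48 if floating-point noise
  left the recomputed value on the wrong side. Directly supplied quantities
  (FEV1, grip, gait, CRP, transferrin, albumin) are probed at the printed
  display precision (0.1, or 0.01 for gait speed).

## What the synthetic cohort does and does not show

`generate_archetypes()` inverts every cutoff to build one patient per
reachable combination of gender × 5 phenotypes × 4 stages × 4 NRI classes ×
7 sarcopenia/cachexia states (1120 patients); the test suite requires the
requested labels to round-trip exactly through `classify_patients()`.
`generate_boundary_cases()` probes both sides of all 21 cutoffs.
`generate_cohort(n, seed)` draws seeded random patients from fixed plausible
ranges (age 40–90 years, FEV1 15–110%, BMI 14–42 kg/m², albumin
2.5–5 g/dL, gait 0.3–1.5 m/s, and so on), chosen once to make cohorts
clinically sensible.

These cohorts exercise every rule path and boundary, which is exactly what a
deterministic rule engine needs. They are **not** an epidemiological
simulation: field values are drawn independently, so joint distributions
(e.g. the correlation between FEV1 and gait speed in real patients) are not
modelled, and passing tests say nothing about how often each branch fires in
a real clinic, only that every branch fires correctly.

## Validation statistics

`summarize_agreement()` reproduces expert-panel Likert summaries: per-item
mean and sample (n−1) standard deviation, and an overall mean and sample SD
of the item means, all rounded half-up to two decimals. This estimator
reproduces every bundled per-profile pair exactly (e.g. profile FG:
mean 3.29, SD 1.38; overall mean 4.23). Problem sizes throughout the test
suite — 10⁵ random inputs for the classifier-versus-oracle sweeps, the full
1120-patient lattice for the recommendation invariants — run in seconds and
were chosen as comfortable desk-scale checks.

## Known limitations

* The engine encodes the Italian guideline context (LARN-relative rules,
  WHO sodium cap); other national rule sets require editing the YAML table.
* Pediatric cutoffs, longitudinal records, medication data, free-text notes
  and activity-adjusted energy expenditure are out of scope; a supplied
  `activity_level` column is carried through untouched, with an advisory.
* The Turtle export writes the `copd:` vocabulary for interoperability but
  the package performs no description-logic reasoning; the rule engine is
  the single source of inference.

## A worked patient

```{r worked}
patient <- tibble::tibble(
  id = "W1", gender = "male", age = 64, current_weight = 70,
  usual_weight = 70, height = 1.75, fev1_percent = 65, hand_grip = 35,
  gait_speed = 1.1, resistance = 430, reactance = 50, albumin = 4.2,
  crp = 2, transferrin = 250
)
assessment <- assess_patients(patient)
assessment[, c("phenotype", "copd_stage", "nri_class", "sarcopenia_level",
               "cachectic", "bmr_kcal", "energy_kcal", "protein_g")]
```

BMI 22.86 kg/m² (normal weight) selects Harris–Benedict: 66.5 + 13.75×70 +
5×175 − 6.78×64 = 1470.08 → 1470 kcal. Stage II and no cachexia give the
1.5 factor: 1470 × 1.5 = 2205 kcal. Protein at 1.2 g/kg of the measured
70 kg is 84 g (15.2% of energy); carbohydrate 45–50% (248.1–275.6 g) and
fat takes the 34.8–39.8% remainder.

```{r trace}
head(rule_trace(assessment)[, c("rule_id", "field", "provenance")], 8)
```
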