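# nutricopd

Nutritional status is a major, and often neglected, determinant of outcome
in chronic obstructive pulmonary disease (COPD): malnutrition, sarcopenia
and cachexia are frequent in these patients and drive exacerbations,
respiratory-muscle weakness and mortality, yet pulmonary-rehabilitation
programs rarely have a dietician at hand. `nutricopd` gives pneumologists
and clinical-nutrition researchers a deterministic, fully explainable rule
engine that turns one routine patient assessment into a classification of
the patient and a fourteen-item tailored nutritional recommendation — with
every number traceable to a named rule whose provenance (clinical guideline
vs. package assumption) is recorded.

## The model

From `id, gender, age, current/usual weight, height, FEV1 %, hand grip,
gait speed, bioimpedance resistance/reactance, albumin, CRP, transferrin`
(optionally pCO2 and two comorbidity flags), the engine infers:

* **Anthropometric phenotype** — WHO BMI categories (underweight < 18.5 …
  obesity degree III ≥ 40 kg/m²);
* **COPD stage** — FEV1 ≥ 80 → I, 50–80 → II, 30–50 → III, < 30 → IV;
* **Nutritional risk index** — NRI = 1.519 × albumin(g/L) + 41.7 ×
  current/usual weight, classed absence (> 100) / mild (97.5–100) /
  moderate (83.5–97.5) / severe (< 83.5);
* **Sarcopenia ladder** — probable (grip < 27 kg M / < 16 kg F), diagnosed
  (+ low muscle mass: Sergi bioimpedance ASMM < 20/15 kg or ASMM/h² <
  7/5.5 kg/m²), severe (+ gait ≤ 0.8 m/s);
* **Cachexia** — sarcopenia plus CRP > 10 mg/L, transferrin < 150 mg/dL,
  albumin < 3.5 g/dL.

The recommendation computes BMR (Harris–Benedict for lean, Mifflin–St Jeor
for overweight/obese phenotypes), total energy (BMR × 1.5 for stages I/II,
× 1.8 for stages III/IV or any cachexia), protein (1.2 g/kg, 1.5 g/kg if
sarcopenic, 25% of energy if cachectic, with reference-BMI weight bases for
underweight and obese patients), carbohydrate 45–50% (40–45% under
hypercapnia), fat by share conservation, sugar ≤ 15% (≤ 10% with type 2
diabetes), saturated fat ≤ 10%, cholesterol ≤ 300 mg (≤ 200 mg with
hypercholesterolemia), fiber 15–25 g, sodium ≤ 2000 mg, calcium 1200 mg,
five meals per day, and BCAA / energy-protein supplementation flags.

## Worked example

```r
library(nutricopd)

patient <- tibble::tibble(
  id = "W1", gender = "male", age = 64, current_weight = 70,
  usual_weight = 70, height = 1.75, fev1_percent = 65, hand_grip = 35,
  gait_speed = 1.1, resistance = 430, reactance = 50, albumin = 4.2,
  crp = 2, transferrin = 250
)
a <- assess_patients(patient)
cat(write_report(a, format = "markdown"))
```

```
## Health condition

- BMI: 22.86 kg/m2 (normal_weight)
- COPD stage: II
- NRI: 105.5 (absence risk class)
- ASMM: 23.44 kg (resistive index 71.22)
- Sarcopenia: none
- Cachectic: no

## Nutritional recommendations

- Basal metabolic rate: 1470 kcal/day
- Total daily energy (x1.5): 2205 kcal/day
- Meals per day: 5
- Energy-protein supplement: no
- BCAA supplement: no
- Protein: 15.2% / 84 g
- Carbohydrate: 45-50% / 248.1-275.6 g
- Fat: 34.8-39.8% / 85.2-97.4 g
- Sugar (max): 15% / 82.7 g
- Saturated fat (max): 10% / 24.5 g
- Cholesterol (max): 300 mg
- Fiber: 15-25 g
- Sodium (max): 2000 mg
- Calcium: 1200 mg
```

A 64-year-old normal-weight man in stage II with no nutritional risk gets
the Harris–Benedict BMR (66.5 + 13.75×70 + 5×175 − 6.78×64 → 1470 kcal),
the 1.5 stage-I/II factor (2205 kcal/day) and 1.2 g protein per kg
(84 g/day). `rule_trace(a)` lists every fired rule per emitted field;
values flagged `assumption` (calcium, fiber, meal count) are the ones the
rule base fixed only directionally.

Other entry points: `generate_cohort()` / `generate_archetypes()` /
`generate_boundary_cases()` build synthetic patients covering every rule
path and cutoff; `read_patients()` / `write_patients()` handle the CSV/JSON
schema; `export_triples()` writes RDF Turtle in the `copd:` vocabulary;
`summarize_agreement()` summarizes expert-panel Likert scores;
`autoplot()`, `tidy()` and `glance()` work on assessment objects. A thin
CLI lives at `inst/cli/nutricopd.R`
(`classify | recommend | cohort | export-ttl | agreement`).

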