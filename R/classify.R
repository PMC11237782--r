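#' Body mass index
#'
#' @param weight body weight in kg (> 0).
#' @param height height in metres (> 0).
#' @return BMI in kg/m^2 at full precision (round only for display).
#' @examples
#' compute_bmi(70, 1.75) # 22.857...
#' @export
compute_bmi <- function(weight, height) {
  stopifnot(is.numeric(weight), is.numeric(height))
  if (any(!is.finite(weight) | weight <= 0)) abort("`weight` must be > 0 kg")
  if (any(!is.finite(height) | height <= 0)) abort("`height` must be > 0 m")
  weight / height^2
}

#' Anthropometric phenotype from BMI
#'
#' WHO nutritional-status categories, normalized to half-open intervals
#' \code{[lo, hi)}: underweight < 18.5, normal weight 18.5-25, overweight
#' 25-30, obesity degree I 30-35, degree II 35-40, degree III >= 40. The rule
#' base defines nutrient branches for five phenotypes; degree-III obesity is
#' still classified but is routed to the degree-II rule set downstream, with a
#' warning here.
#'
#' @param bmi BMI in kg/m^2 (> 0).
#' @return factor with levels `r paste(PHENOTYPE_LEVELS, collapse = ", ")`.
#' @examples
#' classify_phenotype(c(18.5, 24.95, 30))
#' @export
classify_phenotype <- function(bmi) {
  if (any(!is.finite(bmi) | bmi <= 0)) abort("`bmi` must be finite and > 0")
  v <- rule_value
  brk <- c(v("CLS-BMI", "normal_min"), v("CLS-BMI", "overweight_min"),
           v("CLS-BMI", "obesity_1_min"), v("CLS-BMI", "obesity_2_min"),
           v("CLS-BMI", "obesity_3_min"))
  out <- cut(bmi, breaks = c(-Inf, brk, Inf), labels = PHENOTYPE_LEVELS,
             right = FALSE)
  if (any(out == "obesity_3")) {
    warn(paste("BMI >= 40 (obesity degree III) is outside the five-phenotype",
               "rule base; degree-II obesity rules will be applied"))
  }
  out
}

#' COPD stage from FEV1 % of predicted
#'
#' Stage I (mild) FEV1 >= 80, II (moderate) 50-80, III (severe) 30-50,
#' IV (very severe) < 30.
#'
#' @param fev1_percent FEV1 as % of the predicted value (> 0).
#' @return factor with levels I, II, III, IV.
#' @examples
#' stage_copd(c(80, 79.9, 30, 29.9))
#' @export
stage_copd <- function(fev1_percent) {
  if (any(!is.finite(fev1_percent) | fev1_percent <= 0)) {
    abort("`fev1_percent` must be finite and > 0")
  }
  v <- rule_value
  brk <- c(v("CLS-STAGE", "stage_iii_min"), v("CLS-STAGE", "stage_ii_min"),
           v("CLS-STAGE", "stage_i_min"))
  cut(fev1_percent, breaks = c(-Inf, brk, Inf),
      labels = rev(STAGE_LEVELS), right = FALSE) |>
    factor(levels = STAGE_LEVELS) # reorder I..IV
}

#' Nutritional risk index
#'
#' NRI = 1.519 x albumin (g/L) + 41.7 x current/usual weight. Albumin is
#' supplied in g/dL (the usual laboratory unit) and converted to g/L before
#' the 1.519 coefficient is applied.
#'
#' @param albumin serum albumin in g/dL (> 0).
#' @param current_weight current body weight, kg (> 0).
#' @param usual_weight usual body weight, kg (> 0).
#' @return NRI, dimensionless (~100 for a well-nourished patient).
#' @examples
#' compute_nri(4.0, 60, 60) # 102.46
#' @export
compute_nri <- function(albumin, current_weight, usual_weight) {
  if (any(!is.finite(albumin) | albumin <= 0)) abort("`albumin` must be > 0 g/dL")
  if (any(!is.finite(current_weight) | current_weight <= 0)) {
    abort("`current_weight` must be > 0 kg")
  }
  if (any(!is.finite(usual_weight) | usual_weight <= 0)) {
    abort("`usual_weight` must be > 0 kg")
  }
  rule_value("CLS-NRI-EQ", "albumin_coef") * (albumin * 10) +
    rule_value("CLS-NRI-EQ", "weight_ratio_coef") * (current_weight / usual_weight)
}

#' Nutritional risk class from NRI
#'
#' Absence of risk > 100; mild 97.5-100 (both ends included); moderate
#' 83.5-97.5 (97.5 excluded); severe < 83.5.
#'
#' @param nri nutritional risk index (finite).
#' @return factor with levels absence, mild, moderate, severe.
#' @examples
#' classify_nri(c(100, 100.1, 83.5, 83.49))
#' @export
classify_nri <- function(nri) {
  if (any(!is.finite(nri))) abort("`nri` must be finite")
  v <- rule_value
  dplyr::case_when(
    nri > v("CLS-NRI-CLASS", "absence_min_excl") ~ "absence",
    nri >= v("CLS-NRI-CLASS", "mild_min") ~ "mild",
    nri >= v("CLS-NRI-CLASS", "moderate_min") ~ "moderate",
    TRUE ~ "severe"
  ) |> factor(levels = NRI_LEVELS)
}

#' Bioimpedance resistive index
#'
#' RI = height(cm)^2 / resistance, the quantity the Sergi equation consumes.
#'
#' @param height height in metres (> 0).
#' @param resistance bioimpedance resistance in ohm (> 0).
#' @return resistive index, cm^2/ohm.
#' @examples
#' compute_resistive_index(1.75, 500) # 61.25
#' @export
compute_resistive_index <- function(height, resistance) {
  if (any(!is.finite(height) | height <= 0)) abort("`height` must be > 0 m")
  if (any(!is.finite(resistance) | resistance <= 0)) {
    abort("`resistance` must be > 0 ohm")
  }
  (height * 100)^2 / resistance
}

#' Appendicular skeletal muscle mass (Sergi BIA equation)
#'
#' ASMM (kg) = -3.964 + 0.227 x RI + 0.095 x weight + 1.384 x sex +
#' 0.064 x reactance, with sex coded 1 for male and 0 for female.
#'
#' @param ri resistive index, cm^2/ohm (> 0).
#' @param weight body weight, kg.
#' @param gender "male" or "female".
#' @param reactance bioimpedance reactance, ohm.
#' @return estimated ASMM in kg. Implausibly low estimates (< 5 kg) trigger a
#'   warning but are returned unchanged.
#' @examples
#' compute_asmm(61.25, 70, "male", 50) # 21.17...
#' @export
compute_asmm <- function(ri, weight, gender, reactance) {
  if (any(!is.finite(ri) | ri <= 0)) abort("`ri` must be > 0")
  if (!all(gender %in% GENDER_LEVELS)) abort("`gender` must be 'male' or 'female'")
  v <- function(name) rule_value("CLS-ASMM-EQ", name)
  out <- v("intercept") + v("ri_coef") * ri + v("weight_coef") * weight +
    v("male_coef") * as.numeric(gender == "male") + v("reactance_coef") * reactance
  if (any(out < 5)) {
    warn("implausibly low ASMM estimate (< 5 kg); check bioimpedance inputs")
  }
  out
}

#' Sarcopenia ladder
#'
#' Operational definition with three criteria: (1) low muscle strength - hand
#' grip < 27 kg (male) / < 16 kg (female); (2) low muscle quantity - ASMM
#' < 20 kg (male) / < 15 kg (female) *or* ASMM/height^2 < 7 (male) / < 5.5
#' (female) kg/m^2; (3) poor physical performance - gait speed <= 0.8 m/s.
#' Criterion 1 alone gives *probable* sarcopenia, 1 and 2 *diagnosed*, all
#' three *severe*; without criterion 1 the patient is not sarcopenic.
#'
#' @param gender "male" or "female".
#' @param hand_grip hand-grip strength, kg.
#' @param asmm appendicular skeletal muscle mass, kg.
#' @param height height in metres.
#' @param gait_speed gait speed, m/s.
#' @return factor with levels none, probable, diagnosed, severe.
#' @examples
#' assess_sarcopenia("male", 27, 23, 1.75, 1.0)   # none (27 is not < 27)
#' assess_sarcopenia("female", 15, 14, 1.62, 0.9) # diagnosed
#' @export
assess_sarcopenia <- function(gender, hand_grip, asmm, height, gait_speed) {
  if (!all(gender %in% GENDER_LEVELS)) abort("`gender` must be 'male' or 'female'")
  v <- function(name) rule_value("CLS-SARC", name)
  male <- gender == "male"
  c1 <- hand_grip < ifelse(male, v("grip_male"), v("grip_female"))
  c2 <- asmm < ifelse(male, v("asmm_male"), v("asmm_female")) |
    asmm / height^2 < ifelse(male, v("asmm_h2_male"), v("asmm_h2_female"))
  c3 <- gait_speed <= v("gait_max")
  dplyr::case_when(
    !c1 ~ "none",
    c1 & !c2 ~ "probable",
    c1 & c2 & !c3 ~ "diagnosed",
    TRUE ~ "severe"
  ) |> factor(levels = SARC_LEVELS)
}

#' Cachexia flag
#'
#' Cachexia is operationalized as a particular case of sarcopenia: the patient
#' must be sarcopenic (any ladder level above none) *and* show the
#' inflammatory/biochemical triad CRP > 10 mg/L, transferrin < 150 mg/dL and
#' albumin < 3.5 g/dL.
#'
#' @param crp C-reactive protein, mg/L.
#' @param transferrin serum transferrin, mg/dL.
#' @param albumin serum albumin, g/dL.
#' @param sarcopenia_level factor/character from [assess_sarcopenia()].
#' @return logical flag.
#' @examples
#' assess_cachexia(11, 140, 3.4, "diagnosed") # TRUE
#' assess_cachexia(10, 140, 3.4, "severe")    # FALSE (10 is not > 10)
#' @export
assess_cachexia <- function(crp, transferrin, albumin, sarcopenia_level) {
  v <- function(name) rule_value("CLS-CACHEXIA", name)
  crp > v("crp_min_excl") &
    transferrin < v("transferrin_max_excl") &
    albumin < v("albumin_max_excl") &
    as.character(sarcopenia_level) != "none"
}

#' Classify a cohort of patients
#'
#' Runs the whole classification pipeline on validated patient records:
#' BMI and anthropometric phenotype, COPD stage, nutritional risk index and
#' class, resistive index, ASMM, the sarcopenia ladder and the cachexia flag.
#' Input columns are retained, so the result feeds straight into
#' [recommend_nutrition()].
#'
#' @param data validated patient tibble from [validate_patients()] (raw data
#'   frames are validated on the fly).
#' @return The input tibble with classification columns appended: `bmi`,
#'   `phenotype`, `copd_stage`, `nri_value`, `nri_class`, `resistive_index`,
#'   `asmm`, `sarcopenia_level`, `cachectic`. A per-patient rule trace is
#'   attached as attribute `"trace"` (see [rule_trace()]).
#' @examples
#' generate_cohort(5, seed = 1) |> classify_patients()
#' @export
classify_patients <- function(data) {
  p <- validate_patients(data)
  rules <- nutrition_rules()

  out <- dplyr::mutate(
    p,
    bmi = compute_bmi(.data$current_weight, .data$height),
    phenotype = suppressWarnings(classify_phenotype(.data$bmi)),
    copd_stage = stage_copd(.data$fev1_percent),
    nri_value = compute_nri(.data$albumin, .data$current_weight, .data$usual_weight),
    nri_class = classify_nri(.data$nri_value),
    resistive_index = compute_resistive_index(.data$height, .data$resistance),
    asmm = suppressWarnings(
      compute_asmm(.data$resistive_index, .data$current_weight,
                   .data$gender, .data$reactance)),
    sarcopenia_level = assess_sarcopenia(.data$gender, .data$hand_grip,
                                         .data$asmm, .data$height,
                                         .data$gait_speed),
    cachectic = assess_cachexia(.data$crp, .data$transferrin, .data$albumin,
                                .data$sarcopenia_level)
  )
  if (any(out$phenotype == "obesity_3")) {
    warn(paste("BMI >= 40 (obesity degree III) is outside the five-phenotype",
               "rule base; degree-II obesity rules will be applied"))
  }

  trace <- dplyr::bind_rows(
    trace_rows("CLS-BMI", out$id, rules = rules),
    trace_rows("CLS-STAGE", out$id, rules = rules),
    trace_rows("CLS-NRI-EQ", out$id, rules = rules),
    trace_rows("CLS-NRI-CLASS", out$id, rules = rules),
    trace_rows("CLS-ASMM-EQ", out$id, rules = rules),
    trace_rows("CLS-SARC", out$id, rules = rules),
    trace_rows("CLS-CACHEXIA", out$id, rules = rules)
  )
  attr(out, "trace") <- dplyr::arrange(trace, .data$id)
  out
}
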