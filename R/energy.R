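#' Select the BMR predictive equation for a phenotype
#'
#' Harris-Benedict for underweight and normal-weight patients; Mifflin-St Jeor
#' for overweight and obese patients (all obesity degrees).
#'
#' @param phenotype factor/character anthropometric phenotype.
#' @return character vector, "harris_benedict" or "mifflin".
#' @examples
#' select_bmr_equation(c("underweight", "overweight", "obesity_2"))
#' @export
select_bmr_equation <- function(phenotype) {
  phenotype <- as.character(phenotype)
  if (!all(phenotype %in% PHENOTYPE_LEVELS)) {
    abort("unknown phenotype; see ?classify_phenotype")
  }
  ifelse(phenotype %in% c("underweight", "normal_weight"),
         "harris_benedict", "mifflin")
}

#' Basal metabolic rate
#'
#' Harris-Benedict (male: 66.5 + 13.75 x kg + 5 x cm - 6.78 x years; female:
#' 655.1 + 9.563 x kg + 1.850 x cm - 4.676 x years) or Mifflin-St Jeor
#' (10 x kg + 6.25 x cm - 5 x years, + 5 male / - 161 female). The result is
#' rounded half away from zero to a whole kcal/day, mirroring the rule
#' engine's `round` built-in, before any correction factor is applied.
#'
#' @param gender "male" or "female".
#' @param age age in years (> 0).
#' @param weight body weight, kg (> 0).
#' @param height height, metres (> 0).
#' @param equation "harris_benedict" or "mifflin" (from
#'   [select_bmr_equation()]).
#' @return integer kcal/day.
#' @examples
#' compute_bmr("male", 64, 70, 1.75, "harris_benedict") # 1470
#' compute_bmr("male", 60, 90, 1.75, "mifflin")         # 1699
#' @export
compute_bmr <- function(gender, age, weight, height, equation) {
  if (!all(gender %in% GENDER_LEVELS)) abort("`gender` must be 'male' or 'female'")
  if (any(!is.finite(age) | age <= 0)) abort("`age` must be > 0 years")
  if (any(!is.finite(weight) | weight <= 0)) abort("`weight` must be > 0 kg")
  if (any(!is.finite(height) | height <= 0)) abort("`height` must be > 0 m")
  if (!all(equation %in% c("harris_benedict", "mifflin"))) {
    abort("`equation` must be 'harris_benedict' or 'mifflin'")
  }
  n <- max(length(gender), length(age), length(weight), length(height),
           length(equation))
  gender <- rep_len(gender, n); age <- rep_len(age, n)
  weight <- rep_len(weight, n); height <- rep_len(height, n)
  equation <- rep_len(equation, n)
  cm <- height * 100
  v <- rule_value

  hb_m <- v("ENE-HB-MALE", "intercept") + v("ENE-HB-MALE", "weight_coef") * weight +
    v("ENE-HB-MALE", "height_cm_coef") * cm - v("ENE-HB-MALE", "age_coef") * age
  hb_f <- v("ENE-HB-FEMALE", "intercept") + v("ENE-HB-FEMALE", "weight_coef") * weight +
    v("ENE-HB-FEMALE", "height_cm_coef") * cm - v("ENE-HB-FEMALE", "age_coef") * age
  mif <- v("ENE-MIFFLIN", "weight_coef") * weight +
    v("ENE-MIFFLIN", "height_cm_coef") * cm -
    v("ENE-MIFFLIN", "age_coef") * age +
    ifelse(gender == "male", v("ENE-MIFFLIN", "male_offset"),
           v("ENE-MIFFLIN", "female_offset"))

  raw <- ifelse(equation == "mifflin", mif,
                ifelse(gender == "male", hb_m, hb_f))
  as.integer(round_half_up(raw))
}

#' Energy correction factor
#'
#' Multiplier applied to the BMR to obtain the total daily energy requirement:
#' 1.5 for COPD stage I/II, 1.8 for stage III/IV (to counteract the increased
#' respiratory work), and always 1.8 for cachectic patients regardless of
#' stage and phenotype. Sarcopenia alone does not change the factor.
#'
#' @param copd_stage factor/character stage "I".."IV".
#' @param sarcopenia_level sarcopenia ladder level (not used by the current
#'   rule base; accepted to make the rule signature explicit).
#' @param cachectic logical cachexia flag.
#' @return numeric factor, 1.5 or 1.8.
#' @examples
#' correction_factor("II", "none", FALSE)     # 1.5
#' correction_factor("I", "none", TRUE)       # 1.8 (cachexia dominates)
#' @export
correction_factor <- function(copd_stage, sarcopenia_level = "none",
                              cachectic = FALSE) {
  copd_stage <- as.character(copd_stage)
  if (!all(copd_stage %in% STAGE_LEVELS)) abort("`copd_stage` must be I..IV")
  if (!all(as.character(sarcopenia_level) %in% SARC_LEVELS)) {
    abort("unknown sarcopenia level")
  }
  v <- rule_value
  ifelse(cachectic, v("ENE-FACTOR", "cachectic"),
         ifelse(copd_stage %in% c("I", "II"),
                v("ENE-FACTOR", "stage_1_2"), v("ENE-FACTOR", "stage_3_4")))
}

#' Corrected total daily energy requirement
#'
#' Multiplies the already-rounded BMR by the correction factor and rounds
#' again (half away from zero), matching the chaining of the two rounding
#' rules in the engine.
#'
#' @param bmr_kcal rounded BMR in kcal/day (> 0).
#' @param factor correction factor from [correction_factor()].
#' @return integer kcal/day, always >= `bmr_kcal` for factors >= 1.
#' @examples
#' corrected_energy(1470, 1.5) # 2205
#' corrected_energy(1699, 1.8) # 3058
#' @export
corrected_energy <- function(bmr_kcal, factor) {
  if (any(!is.finite(bmr_kcal) | bmr_kcal <= 0)) abort("`bmr_kcal` must be > 0")
  if (any(!is.finite(factor) | factor < 1)) abort("`factor` must be >= 1")
  as.integer(round_half_up(bmr_kcal * factor))
}
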