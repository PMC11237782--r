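#' Protein targets
#'
#' Cachectic patients receive a fixed 25% protein share (grams derived at
#' 4 kcal/g from the corrected energy). All other patients receive grams per
#' kg of a phenotype-dependent basis weight: the measured current weight for
#' normal weight and overweight, the weight at a corrective reference BMI of
#' 22.5 kg/m^2 for underweight, and the ideal weight at BMI 25 kg/m^2 for the
#' obesity classes. The multiplier is 1.2 g/kg, raised to 1.5 g/kg for
#' sarcopenic (non-cachectic) patients. When the share is not fixed at 25% it
#' is derived as grams x 4 / energy x 100.
#'
#' @param phenotype anthropometric phenotype (factor/character).
#' @param sarcopenia_level sarcopenia ladder level.
#' @param cachectic logical cachexia flag.
#' @param energy_kcal corrected daily energy, kcal (> 0).
#' @param weight current weight, kg.
#' @param height height, m.
#' @return tibble with `protein_g` (g/day) and `protein_share` (% of energy).
#' @examples
#' protein_targets("normal_weight", "none", FALSE, 2205, 70, 1.75)
#' protein_targets("underweight", "none", FALSE, 2000, 48, 1.75)
#' @export
protein_targets <- function(phenotype, sarcopenia_level, cachectic,
                            energy_kcal, weight, height) {
  phenotype <- as.character(phenotype)
  sarc <- as.character(sarcopenia_level) != "none"
  if (any(!is.finite(energy_kcal) | energy_kcal <= 0)) {
    abort("`energy_kcal` must be > 0")
  }
  v <- rule_value
  kcal_prot <- v("NUT-KCAL-PER-G", "protein")

  basis <- dplyr::case_when(
    phenotype == "underweight" ~ v("NUT-PROT-REFBMI-UNDER", "reference_bmi") * height^2,
    phenotype %in% c("normal_weight", "overweight") ~ weight,
    TRUE ~ v("NUT-PROT-REFBMI-OBESE", "reference_bmi") * height^2
  )
  g_per_kg <- ifelse(sarc, v("NUT-PROT-GPKG-SARC", "g_per_kg"),
                     v("NUT-PROT-GPKG", "g_per_kg"))

  grams <- ifelse(cachectic,
                  v("NUT-PROT-CACHECTIC", "share") / 100 * energy_kcal / kcal_prot,
                  g_per_kg * basis)
  share <- ifelse(cachectic, v("NUT-PROT-CACHECTIC", "share"),
                  grams * kcal_prot / energy_kcal * 100)
  tibble::tibble(protein_g = grams, protein_share = share)
}

#' Macronutrient energy shares
#'
#' Carbohydrate is kept at 45-50% of total energy, shifted down to 40-45%
#' under hypercapnia (pCO2 > 50 mm Hg) to favour lipid oxidation, which
#' produces less carbon dioxide per kcal. Fat takes the remainder so the
#' shares are conserved: `fat_share_min = 100 - protein - carb_max` and
#' `fat_share_max = 100 - protein - carb_min`. Simple sugars are capped at
#' 15% of energy, 10% under type 2 diabetes; saturated fat at 10%.
#'
#' @param protein_share protein share, % of energy.
#' @param pco2 partial pressure of CO2, mm Hg; `NA` (not acquired) is treated
#'   as normocapnic.
#' @param has_t2dm logical type 2 diabetes flag.
#' @return tibble with `carb_share_min`, `carb_share_max`, `fat_share_min`,
#'   `fat_share_max`, `sugar_share_max`, `satfat_share_max` (all %).
#' @examples
#' energy_shares(15.24)
#' energy_shares(25, pco2 = 55)
#' @export
energy_shares <- function(protein_share, pco2 = NA_real_, has_t2dm = FALSE) {
  if (any(!is.finite(protein_share) | protein_share <= 0)) {
    abort("`protein_share` must be > 0")
  }
  v <- rule_value
  n <- max(length(protein_share), length(pco2), length(has_t2dm))
  protein_share <- rep_len(protein_share, n)
  pco2 <- rep_len(pco2, n)
  has_t2dm <- rep_len(has_t2dm, n)

  hypercapnic <- !is.na(pco2) & pco2 > v("NUT-CARB-PCO2", "pco2_cutoff")
  shift <- v("NUT-CARB-PCO2", "shift_points")
  carb_min <- ifelse(hypercapnic, v("NUT-CARB", "share_min") - shift,
                     v("NUT-CARB", "share_min"))
  carb_max <- ifelse(hypercapnic, v("NUT-CARB", "share_max") - shift,
                     v("NUT-CARB", "share_max"))
  fat_min <- 100 - protein_share - carb_max
  fat_max <- 100 - protein_share - carb_min
  if (any(fat_min < 0)) {
    abort(paste0(
      "infeasible share set: protein share ",
      paste(round(protein_share[fat_min < 0], 1), collapse = ", "),
      "% exceeds 100% minus the carbohydrate band (rules NUT-PROT-*, NUT-CARB",
      ifelse(any(hypercapnic[fat_min < 0]), ", NUT-CARB-PCO2", ""), ")"
    ))
  }
  tibble::tibble(
    carb_share_min = carb_min, carb_share_max = carb_max,
    fat_share_min = fat_min, fat_share_max = fat_max,
    sugar_share_max = ifelse(has_t2dm, v("NUT-SUGAR-T2DM", "share_max"),
                             v("NUT-SUGAR", "share_max")),
    satfat_share_max = rep(v("NUT-SATFAT", "share_max"), n)
  )
}

#' Micronutrient caps and fiber band
#'
#' Cholesterol is capped at 300 mg/day, lowered to 200 mg/day under
#' hypercholesterolemia; sodium at 2000 mg/day (WHO); calcium is set at
#' 1200 mg/day (deliberately above the Italian LARN reference, against
#' osteoporosis) and fiber at 15-25 g/day (deliberately below the LARN
#' reference, to spare early satiety).
#'
#' @param has_hypercholesterolemia logical flag.
#' @return tibble with `cholesterol_max_mg`, `sodium_max_mg`, `calcium_mg`,
#'   `fiber_min_g`, `fiber_max_g`.
#' @examples
#' micronutrient_caps()
#' micronutrient_caps(TRUE)
#' @export
micronutrient_caps <- function(has_hypercholesterolemia = FALSE) {
  v <- rule_value
  n <- length(has_hypercholesterolemia)
  tibble::tibble(
    cholesterol_max_mg = ifelse(has_hypercholesterolemia,
                                v("NUT-CHOL-HC", "max_mg"),
                                v("NUT-CHOL", "max_mg")),
    sodium_max_mg = rep(v("NUT-SODIUM", "max_mg"), n),
    calcium_mg = rep(v("NUT-CALCIUM", "mg"), n),
    fiber_min_g = rep(v("NUT-FIBER", "min_g"), n),
    fiber_max_g = rep(v("NUT-FIBER", "max_g"), n)
  )
}

#' Supplementation flags
#'
#' Cachexia always triggers both BCAA and energy-protein supplementation,
#' regardless of phenotype and stage. Sarcopenic underweight or normal-weight
#' patients also receive both; any other sarcopenic phenotype receives BCAA
#' only. Non-sarcopenic, non-cachectic patients receive neither.
#'
#' @param phenotype anthropometric phenotype.
#' @param sarcopenia_level sarcopenia ladder level.
#' @param cachectic logical cachexia flag.
#' @return tibble with logical `bcaa_supplement` and
#'   `energy_protein_supplement`.
#' @examples
#' supplementation_flags("obesity_1", "none", TRUE)     # both
#' supplementation_flags("overweight", "diagnosed", FALSE) # BCAA only
#' @export
supplementation_flags <- function(phenotype, sarcopenia_level, cachectic) {
  phenotype <- as.character(phenotype)
  sarc <- as.character(sarcopenia_level) != "none"
  lean <- phenotype %in% c("underweight", "normal_weight")
  tibble::tibble(
    bcaa_supplement = cachectic | sarc,
    energy_protein_supplement = cachectic | (sarc & lean)
  )
}

#' Assemble the fourteen-item nutritional recommendation
#'
#' Runs the energy module (equation selection, BMR, correction factor,
#' corrected energy) and every nutrient rule on classified patients, then
#' converts shares to grams at 4 kcal/g for protein, carbohydrate and sugar
#' and 9 kcal/g for fat and saturated fat. Grams are reported to 0.1 g.
#' Degree-III obesity is routed through the degree-II rule set (the rule base
#' defines five phenotypes).
#'
#' @param data classified patient tibble from [classify_patients()] (raw or
#'   validated records are classified on the fly).
#' @return The input tibble with recommendation columns appended: `bmr_kcal`,
#'   `energy_factor`, `energy_kcal`, `meals_per_day`,
#'   `energy_protein_supplement`, `bcaa_supplement`, `protein_share`,
#'   `protein_g`, `carb_share_min/max`, `carb_g_min/max`, `fat_share_min/max`,
#'   `fat_g_min/max`, `sugar_share_max`, `sugar_g_max`, `satfat_share_max`,
#'   `satfat_g_max`, `cholesterol_max_mg`, `fiber_min_g`, `fiber_max_g`,
#'   `sodium_max_mg`, `calcium_mg`. The classification trace is extended with
#'   every fired nutrient rule and kept in attribute `"trace"`.
#' @examples
#' generate_cohort(3, seed = 1) |> classify_patients() |> recommend_nutrition()
#' @export
recommend_nutrition <- function(data) {
  if (!all(c("phenotype", "copd_stage", "sarcopenia_level", "cachectic")
           %in% names(data))) {
    data <- classify_patients(data)
  }
  rules <- nutrition_rules()
  v <- rule_value
  trace <- attr(data, "trace") %||%
    tibble::tibble(id = character(), rule_id = character(),
                   description = character(), field = character(),
                   provenance = character())

  # degree-III obesity handled by the degree-II branch
  eff_phen <- as.character(data$phenotype)
  eff_phen[eff_phen == "obesity_3"] <- "obesity_2"

  equation <- select_bmr_equation(eff_phen)
  bmr <- compute_bmr(data$gender, data$age, data$current_weight,
                     data$height, equation)
  factor <- correction_factor(data$copd_stage, data$sarcopenia_level,
                              data$cachectic)
  energy <- corrected_energy(bmr, factor)

  prot <- protein_targets(eff_phen, data$sarcopenia_level, data$cachectic,
                          energy, data$current_weight, data$height)
  shares <- energy_shares(prot$protein_share, data$pco2, data$has_t2dm)
  caps <- micronutrient_caps(data$has_hypercholesterolemia)
  supp <- supplementation_flags(eff_phen, data$sarcopenia_level,
                                data$cachectic)

  kc <- v("NUT-KCAL-PER-G", "carbohydrate")
  kf <- v("NUT-KCAL-PER-G", "fat")
  g1 <- function(x) round_half_up(x, 1)

  out <- dplyr::bind_cols(
    data,
    tibble::tibble(
      bmr_equation = equation,
      bmr_kcal = bmr,
      energy_factor = factor,
      energy_kcal = energy,
      meals_per_day = as.integer(v("NUT-MEALS", "meals"))
    ),
    supp["energy_protein_supplement"], supp["bcaa_supplement"],
    tibble::tibble(
      protein_share = prot$protein_share,
      protein_g = g1(prot$protein_g)
    ),
    shares[c("carb_share_min", "carb_share_max")],
    tibble::tibble(
      carb_g_min = g1(shares$carb_share_min / 100 * energy / kc),
      carb_g_max = g1(shares$carb_share_max / 100 * energy / kc)
    ),
    shares[c("fat_share_min", "fat_share_max")],
    tibble::tibble(
      fat_g_min = g1(shares$fat_share_min / 100 * energy / kf),
      fat_g_max = g1(shares$fat_share_max / 100 * energy / kf)
    ),
    shares["sugar_share_max"],
    tibble::tibble(sugar_g_max = g1(shares$sugar_share_max / 100 * energy / kc)),
    shares["satfat_share_max"],
    tibble::tibble(satfat_g_max = g1(shares$satfat_share_max / 100 * energy / kf)),
    caps
  )

  sarc <- as.character(data$sarcopenia_level) != "none"
  cach <- data$cachectic
  hypercapnic <- !is.na(data$pco2) & data$pco2 > v("NUT-CARB-PCO2", "pco2_cutoff")
  tr <- function(rule, which) {
    if (!any(which)) return(tibble::tibble())
    trace_rows(rule, data$id[which], rules = rules)
  }
  trace <- dplyr::bind_rows(
    trace,
    tr("ENE-HB-MALE", equation == "harris_benedict" & data$gender == "male"),
    tr("ENE-HB-FEMALE", equation == "harris_benedict" & data$gender == "female"),
    tr("ENE-MIFFLIN", equation == "mifflin"),
    trace_rows("ENE-FACTOR", data$id, rules = rules),
    trace_rows("NUT-KCAL-PER-G", data$id, rules = rules),
    tr("NUT-PROT-CACHECTIC", cach),
    tr("NUT-PROT-GPKG", !cach & !sarc),
    tr("NUT-PROT-GPKG-SARC", !cach & sarc),
    tr("NUT-PROT-REFBMI-UNDER", !cach & eff_phen == "underweight"),
    tr("NUT-PROT-REFBMI-OBESE", !cach & eff_phen %in% c("obesity_1", "obesity_2")),
    tr("NUT-CARB", !hypercapnic),
    tr("NUT-CARB-PCO2", hypercapnic),
    tr("NUT-SUGAR", !out$has_t2dm),
    tr("NUT-SUGAR-T2DM", out$has_t2dm),
    trace_rows("NUT-SATFAT", data$id, rules = rules),
    tr("NUT-CHOL", !out$has_hypercholesterolemia),
    tr("NUT-CHOL-HC", out$has_hypercholesterolemia),
    trace_rows("NUT-SODIUM", data$id, rules = rules),
    trace_rows("NUT-CALCIUM", data$id, rules = rules),
    trace_rows("NUT-FIBER", data$id, rules = rules),
    trace_rows("NUT-MEALS", data$id, rules = rules),
    tr("NUT-SUPP-CACHECTIC", cach),
    tr("NUT-SUPP-SARC-LEAN", !cach & sarc &
         eff_phen %in% c("underweight", "normal_weight")),
    tr("NUT-SUPP-SARC", !cach & sarc),
    tr("NUT-SUPP-DEFAULT", !cach & !sarc),
    # sarcopenic non-lean phenotypes: BCAA fires but the energy-protein
    # default (no) still needs its provenance entry
    {
      w <- !cach & sarc & !eff_phen %in% c("underweight", "normal_weight")
      if (any(w)) trace_rows("NUT-SUPP-DEFAULT", data$id[w],
                             fields = "energy_protein_supplement",
                             rules = rules) else tibble::tibble()
    }
  )
  attr(out, "trace") <- dplyr::arrange(trace, .data$id)
  out
}
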