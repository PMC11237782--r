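# shared fixtures and independent oracles (deliberately written as nested
# conditionals / explicit lookup tables, not as interval maps, so they can
# disagree with the engine if either is wrong)

worked_patient <- function(id = "W1", ...) {
  p <- tibble::tibble(
    id = id, gender = "male", age = 64, current_weight = 70,
    usual_weight = 70, height = 1.75, fev1_percent = 65, hand_grip = 35,
    gait_speed = 1.1, resistance = 430, reactance = 50, albumin = 4.2,
    crp = 2, transferrin = 250
  )
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}

oracle_phenotype <- function(bmi) {
  if (bmi < 18.5) "underweight"
  else if (bmi < 25) "normal_weight"
  else if (bmi < 30) "overweight"
  else if (bmi < 35) "obesity_1"
  else if (bmi < 40) "obesity_2"
  else "obesity_3"
}

oracle_stage <- function(fev1) {
  if (fev1 >= 80) "I"
  else if (fev1 >= 50) "II"
  else if (fev1 >= 30) "III"
  else "IV"
}

oracle_nri_class <- function(nri) {
  if (nri > 100) "absence"
  else if (nri >= 97.5) "mild"
  else if (nri >= 83.5) "moderate"
  else "severe"
}

oracle_sarcopenia <- function(gender, grip, asmm, height, gait) {
  if (gender == "male") {
    c1 <- grip < 27
    c2 <- asmm < 20 || asmm / height^2 < 7
  } else {
    c1 <- grip < 16
    c2 <- asmm < 15 || asmm / height^2 < 5.5
  }
  c3 <- gait <= 0.8
  if (!c1) "none"
  else if (!c2) "probable"
  else if (!c3) "diagnosed"
  else "severe"
}

# flat decision-table oracle for the recommendation block, one scalar patient
# at a time; constants restated independently of the rule table
oracle_recommendation <- function(phenotype, stage, sarc_level, cachectic,
                                  gender, age, weight, height,
                                  pco2 = NA, t2dm = FALSE, hc = FALSE) {
  rh <- function(x, d = 0) sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d
  cm <- height * 100
  if (phenotype == "obesity_3") phenotype <- "obesity_2"

  bmr <- if (phenotype %in% c("underweight", "normal_weight")) {
    if (gender == "male") 66.5 + 13.75 * weight + 5 * cm - 6.78 * age
    else 655.1 + 9.563 * weight + 1.850 * cm - 4.676 * age
  } else {
    10 * weight + 6.25 * cm - 5 * age + (if (gender == "male") 5 else -161)
  }
  bmr <- rh(bmr)

  factor_table <- data.frame(
    stage = rep(c("I", "II", "III", "IV"), 2),
    cach = rep(c(FALSE, TRUE), each = 4),
    f = c(1.5, 1.5, 1.8, 1.8, 1.8, 1.8, 1.8, 1.8)
  )
  f <- factor_table$f[factor_table$stage == stage &
                        factor_table$cach == cachectic]
  energy <- rh(bmr * f)

  if (cachectic) {
    prot_share <- 25
    prot_g <- 25 / 100 * energy / 4
  } else {
    basis <- switch(phenotype,
                    underweight = 22.5 * height^2,
                    normal_weight = weight,
                    overweight = weight,
                    obesity_1 = 25 * height^2,
                    obesity_2 = 25 * height^2)
    gpk <- if (sarc_level == "none") 1.2 else 1.5
    prot_g <- gpk * basis
    prot_share <- prot_g * 4 / energy * 100
  }

  hyperc <- !is.na(pco2) && pco2 > 50
  carb_min <- if (hyperc) 40 else 45
  carb_max <- if (hyperc) 45 else 50
  list(
    bmr_kcal = bmr, energy_factor = f, energy_kcal = energy,
    protein_g = rh(prot_g, 1), protein_share = prot_share,
    carb_share_min = carb_min, carb_share_max = carb_max,
    fat_share_min = 100 - prot_share - carb_max,
    fat_share_max = 100 - prot_share - carb_min,
    sugar_share_max = if (t2dm) 10 else 15,
    satfat_share_max = 10,
    cholesterol_max_mg = if (hc) 200 else 300,
    sodium_max_mg = 2000, calcium_mg = 1200,
    fiber_min_g = 15, fiber_max_g = 25, meals_per_day = 5,
    bcaa = cachectic || sarc_level != "none",
    energy_protein = cachectic ||
      (sarc_level != "none" &&
         phenotype %in% c("underweight", "normal_weight"))
  )
}

# seeded random scalar inputs for property tests
random_classification_inputs <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    bmi = runif(n, 10, 55),
    fev1 = runif(n, 5, 130),
    nri = runif(n, 40, 130),
    gender = sample(c("male", "female"), n, replace = TRUE),
    grip = runif(n, 0, 60),
    asmm = runif(n, 5, 35),
    height = runif(n, 1.4, 2.0),
    gait = runif(n, 0.1, 2.0)
  )
}
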