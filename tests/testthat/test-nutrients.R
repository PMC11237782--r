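test_that("protein targets follow the phenotype/status branches", {
  # normal weight, non-sarcopenic, non-cachectic: 1.2 g/kg of current weight
  p <- protein_targets("normal_weight", "none", FALSE, 2205, 70, 1.75)
  expect_equal(p$protein_g, 84)
  expect_equal(p$protein_share, 84 * 4 / 2205 * 100) # 15.24%
  # cachectic: fixed 25% share, grams derived at 4 kcal/g
  p <- protein_targets("obesity_1", "diagnosed", TRUE, 2000, 90, 1.70)
  expect_equal(p$protein_share, 25)
  expect_equal(p$protein_g, 125)
  # underweight: basis weight at reference BMI 22.5
  p <- protein_targets("underweight", "none", FALSE, 2000, 48, 1.75)
  expect_equal(p$protein_g, 1.2 * 22.5 * 1.75^2) # 82.6875
  # obese: ideal weight at BMI 25
  p <- protein_targets("obesity_2", "none", FALSE, 2800, 110, 1.70)
  expect_equal(p$protein_g, 1.2 * 25 * 1.70^2)
  # sarcopenic non-cachectic: multiplier raised to 1.5
  p <- protein_targets("overweight", "probable", FALSE, 2500, 80, 1.70)
  expect_equal(p$protein_g, 1.5 * 80)
  expect_error(protein_targets("normal_weight", "none", FALSE, 0, 70, 1.75),
               "energy")
})

test_that("energy shares conserve 100% and react to pCO2 and T2DM", {
  s <- energy_shares(15.24)
  expect_equal(s$carb_share_min, 45)
  expect_equal(s$carb_share_max, 50)
  expect_equal(15.24 + s$carb_share_max + s$fat_share_min, 100)
  expect_equal(15.24 + s$carb_share_min + s$fat_share_max, 100)
  expect_equal(s$sugar_share_max, 15)
  expect_equal(s$satfat_share_max, 10)
  # hypercapnia: 5-point shift from carbohydrate to fat
  s <- energy_shares(25, pco2 = 55)
  expect_equal(c(s$carb_share_min, s$carb_share_max), c(40, 45))
  expect_equal(c(s$fat_share_min, s$fat_share_max), c(30, 35))
  # pCO2 exactly 50 or absent: no shift
  expect_equal(energy_shares(20, pco2 = 50)$carb_share_min, 45)
  expect_equal(energy_shares(20, pco2 = NA)$carb_share_min, 45)
  expect_equal(energy_shares(20, has_t2dm = TRUE)$sugar_share_max, 10)
  expect_error(energy_shares(60), "infeasible")
})

test_that("micronutrient caps", {
  caps <- micronutrient_caps(FALSE)
  expect_equal(caps$cholesterol_max_mg, 300)
  expect_equal(caps$sodium_max_mg, 2000)
  expect_equal(caps$calcium_mg, 1200)
  expect_equal(c(caps$fiber_min_g, caps$fiber_max_g), c(15, 25))
  expect_equal(micronutrient_caps(TRUE)$cholesterol_max_mg, 200)
  # flags are independent: sodium never moves
  expect_equal(micronutrient_caps(c(TRUE, FALSE))$sodium_max_mg, c(2000, 2000))
})

test_that("supplementation flags", {
  f <- supplementation_flags("obesity_1", "none", TRUE) # cachectic, any BMI
  expect_true(f$bcaa_supplement && f$energy_protein_supplement)
  f <- supplementation_flags("overweight", "diagnosed", FALSE)
  expect_true(f$bcaa_supplement)
  expect_false(f$energy_protein_supplement)
  f <- supplementation_flags("normal_weight", "probable", FALSE)
  expect_true(f$bcaa_supplement && f$energy_protein_supplement)
  f <- supplementation_flags("normal_weight", "none", FALSE)
  expect_false(f$bcaa_supplement || f$energy_protein_supplement)
})

test_that("the worked normal-weight patient chains to the printed numbers", {
  a <- assess_patients(worked_patient())
  expect_equal(a$bmr_kcal, 1470L)
  expect_equal(a$energy_factor, 1.5)
  expect_equal(a$energy_kcal, 2205L)
  expect_equal(a$protein_g, 84)
  expect_equal(a$carb_g_min, 248.1)
  expect_equal(a$carb_g_max, 275.6)
  expect_equal(a$sodium_max_mg, 2000)
  expect_equal(a$meals_per_day, 5L)
})

test_that("assessment is deterministic", {
  p <- generate_cohort(5, seed = 9)
  a1 <- suppressWarnings(assess_patients(p)) # random BMI may exceed 40
  a2 <- suppressWarnings(assess_patients(p))
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  expect_identical(rule_trace(a1), rule_trace(a2))
})

test_that("cachexia dominance: factor, share and supplements co-fire", {
  arch <- generate_archetypes()
  a <- recommend_nutrition(classify_patients(arch))
  cach <- a$target_cachectic
  expect_true(all(a$energy_factor[cach] == 1.8))
  expect_true(all(a$protein_share[cach] == 25))
  expect_true(all(a$bcaa_supplement[cach]))
  expect_true(all(a$energy_protein_supplement[cach]))
})

RECOMMENDATION_FIELDS <- c(
  "bmr_kcal", "energy_kcal", "meals_per_day", "energy_protein_supplement",
  "bcaa_supplement", "protein_share", "protein_g", "carb_share_min",
  "carb_share_max", "carb_g_min", "carb_g_max", "fat_share_min",
  "fat_share_max", "fat_g_min", "fat_g_max", "sugar_share_max", "sugar_g_max",
  "satfat_share_max", "satfat_g_max", "cholesterol_max_mg", "fiber_min_g",
  "fiber_max_g", "sodium_max_mg", "calcium_mg")

test_that("the full lattice yields complete recommendations with conserved shares", {
  arch <- generate_archetypes()
  # widen the lattice with the comorbidity flags and hypercapnia
  arch$has_t2dm <- rep_len(c(FALSE, TRUE), nrow(arch))
  arch$has_hypercholesterolemia <- rep_len(c(FALSE, FALSE, TRUE), nrow(arch))
  arch$pco2 <- rep_len(c(NA, 45, 55), nrow(arch))
  a <- recommend_nutrition(classify_patients(arch))
  # completeness: no unassigned field anywhere
  for (f in RECOMMENDATION_FIELDS) expect_false(anyNA(a[[f]]), info = f)
  # share conservation at both ends of the carbohydrate band
  expect_equal(a$protein_share + a$carb_share_max + a$fat_share_min,
               rep(100, nrow(a)), tolerance = 1e-8)
  expect_equal(a$protein_share + a$carb_share_min + a$fat_share_max,
               rep(100, nrow(a)), tolerance = 1e-8)
  # gram conversions at 4 kcal/g (protein, carb, sugar) and 9 kcal/g (fat)
  expect_true(all(abs(a$protein_g - a$protein_share / 100 * a$energy_kcal / 4)
                  <= 0.5))
  expect_true(all(abs(a$carb_g_min - a$carb_share_min / 100 * a$energy_kcal / 4) <= 0.5))
  expect_true(all(abs(a$carb_g_max - a$carb_share_max / 100 * a$energy_kcal / 4) <= 0.5))
  expect_true(all(abs(a$fat_g_min - a$fat_share_min / 100 * a$energy_kcal / 9) <= 0.5))
  expect_true(all(abs(a$fat_g_max - a$fat_share_max / 100 * a$energy_kcal / 9) <= 0.5))
  expect_true(all(abs(a$sugar_g_max - a$sugar_share_max / 100 * a$energy_kcal / 4) <= 0.5))
  expect_true(all(abs(a$satfat_g_max - a$satfat_share_max / 100 * a$energy_kcal / 9) <= 0.5))
  # caps
  expect_true(all(a$sugar_share_max <= 15))
  expect_true(all(a$satfat_share_max == 10))
  expect_true(all(a$energy_kcal >= a$bmr_kcal))
  # every recommendation field is covered by at least one trace entry
  tr <- rule_trace(a)
  for (pid in a$id[seq(1, nrow(a), by = 97)]) {
    covered <- tr$field[tr$id == pid]
    expect_true(all(RECOMMENDATION_FIELDS %in% covered), info = pid)
  }
})

test_that("the rule engine agrees with the flat decision-table oracle on the lattice", {
  arch <- generate_archetypes()
  arch$has_t2dm <- rep_len(c(FALSE, TRUE), nrow(arch))
  arch$has_hypercholesterolemia <- rep_len(c(FALSE, TRUE), nrow(arch))
  arch$pco2 <- rep_len(c(NA, 55), nrow(arch))
  a <- recommend_nutrition(classify_patients(arch))
  for (i in seq_len(nrow(a))) {
    o <- oracle_recommendation(
      a$target_phenotype[i], a$target_stage[i], a$target_sarcopenia[i],
      a$target_cachectic[i], a$gender[i], a$age[i], a$current_weight[i],
      a$height[i], a$pco2[i], a$has_t2dm[i], a$has_hypercholesterolemia[i])
    expect_equal(a$bmr_kcal[i], o$bmr_kcal, info = i)
    expect_equal(a$energy_factor[i], o$energy_factor, info = i)
    expect_equal(a$energy_kcal[i], o$energy_kcal, info = i)
    expect_equal(a$protein_g[i], o$protein_g, tolerance = 1e-8, info = i)
    expect_equal(a$protein_share[i], o$protein_share, tolerance = 1e-6,
                 info = i)
    expect_equal(a$carb_share_min[i], o$carb_share_min, info = i)
    expect_equal(a$carb_share_max[i], o$carb_share_max, info = i)
    expect_equal(a$fat_share_min[i], o$fat_share_min, tolerance = 1e-6,
                 info = i)
    expect_equal(a$fat_share_max[i], o$fat_share_max, tolerance = 1e-6,
                 info = i)
    expect_equal(a$sugar_share_max[i], o$sugar_share_max, info = i)
    expect_equal(a$cholesterol_max_mg[i], o$cholesterol_max_mg, info = i)
    expect_equal(a$sodium_max_mg[i], o$sodium_max_mg, info = i)
    expect_equal(a$calcium_mg[i], o$calcium_mg, info = i)
    expect_equal(a$bcaa_supplement[i], o$bcaa, info = i)
    expect_equal(a$energy_protein_supplement[i], o$energy_protein, info = i)
  }
})

test_that("degree-III obesity is routed through the degree-II branch", {
  p <- worked_patient(current_weight = 130, usual_weight = 130)
  expect_warning(a <- assess_patients(p), "degree-II")
  expect_equal(as.character(a$phenotype), "obesity_3")
  expect_equal(a$bmr_equation, "mifflin")
  expect_equal(a$protein_g, round_half_up(1.2 * 25 * 1.75^2, 1))
})
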