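# Synthetic patients with controlled classification outcomes. Every cutoff in
# the rule base is inverted constructively, so every rule path and boundary is
# testable without external data.

# mid-interval anchors used when inverting the cutoff tables
ARCHETYPE_ANCHORS <- list(
  bmi = c(underweight = 17, normal_weight = 21.7, overweight = 27.5,
          obesity_1 = 32.5, obesity_2 = 37.5),
  fev1 = c(I = 90, II = 65, III = 40, IV = 22),
  nri = c(absence = 105, mild = 98.75, moderate = 90.5, severe = 78),
  height = c(male = 1.75, female = 1.62),
  grip_ok = c(male = 35, female = 25),
  grip_low = c(male = 20, female = 12),
  asmm_ok = c(male = 23, female = 19),
  asmm_low = c(male = 15, female = 10)
)

# resistance that makes the Sergi equation hit `asmm_target`, nudged so the
# recomputed ASMM does not fall on the wrong side of the target
solve_resistance <- function(asmm_target, weight, gender, reactance, height) {
  v <- function(name) rule_value("CLS-ASMM-EQ", name)
  need <- asmm_target - v("intercept") - v("weight_coef") * weight -
    v("male_coef") * as.numeric(gender == "male") -
    v("reactance_coef") * reactance
  if (any(need <= 0)) abort("ASMM target not reachable with these inputs")
  ri <- need / v("ri_coef")
  res <- (height * 100)^2 / ri
  for (k in 1:5) {
    got <- compute_asmm(compute_resistive_index(height, res), weight, gender,
                        reactance)
    low <- got < asmm_target
    if (!any(low)) break
    res[low] <- res[low] * (1 - 2^-48)
  }
  res
}

# albumin (ratio fixed at 1) landing the NRI exactly at `nri_target`, nudged
# onto the inclusive side of the classification boundary when needed
solve_albumin_for_nri <- function(nri_target) {
  coef_alb <- rule_value("CLS-NRI-EQ", "albumin_coef") * 10
  coef_ratio <- rule_value("CLS-NRI-EQ", "weight_ratio_coef")
  alb <- (nri_target - coef_ratio) / coef_alb
  for (k in 1:5) {
    got <- compute_nri(alb, 60, 60)
    over <- got > nri_target
    under <- got < nri_target
    if (!any(over | under)) break
    alb[over] <- alb[over] * (1 - 2^-48)
    alb[under] <- alb[under] * (1 + 2^-48)
  }
  alb
}

#' Archetype patients for every reachable classification
#'
#' Builds one synthetic patient per reachable combination of gender x
#' anthropometric phenotype (5 rule-base classes) x COPD stage x NRI class x
#' sarcopenia level x cachexia flag, by inverting the published cutoffs:
#' weight is chosen mid-interval of the target BMI class, FEV1 mid-stage,
#' albumin/weight-ratio solve the NRI equation for a mid-class value, and
#' bioimpedance resistance solves the Sergi equation for an ASMM on the
#' intended side of the low-muscle-quantity cutoffs. Cachectic targets use the
#' inflammatory triad (CRP 20 mg/L, transferrin 100 mg/dL, albumin 3.0 g/dL);
#' combinations with cachexia but no sarcopenia are infeasible (cachexia is a
#' particular case of sarcopenia) and are not generated.
#'
#' @return tibble of patient inputs plus the requested labels in columns
#'   `target_phenotype`, `target_stage`, `target_nri_class`, `target_sarcopenia`,
#'   `target_cachectic`. The round trip `classify_patients()` must reproduce
#'   the targets exactly.
#' @examples
#' arch <- generate_archetypes()
#' nrow(arch) # 2 genders x 5 phenotypes x 4 stages x 4 NRI x 7 status combos
#' @export
generate_archetypes <- function() {
  a <- ARCHETYPE_ANCHORS
  status <- tibble::tibble(
    sarcopenia = c("none", "probable", "diagnosed", "severe",
                   "probable", "diagnosed", "severe"),
    cachectic = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  )
  grid <- tidyr::expand_grid(
    gender = GENDER_LEVELS,
    phenotype = names(a$bmi),
    stage = names(a$fev1),
    nri_class = names(a$nri),
    status
  )

  coef_alb <- rule_value("CLS-NRI-EQ", "albumin_coef") * 10
  coef_ratio <- rule_value("CLS-NRI-EQ", "weight_ratio_coef")
  cach_albumin <- 3.0

  out <- dplyr::mutate(
    grid,
    height = unname(a$height[.data$gender]),
    current_weight = unname(a$bmi[.data$phenotype]) * .data$height^2,
    fev1_percent = unname(a$fev1[.data$stage]),
    age = 65,
    # NRI inversion: non-cachectic patients keep ratio 1 and solve albumin;
    # cachectic patients fix albumin below 3.5 and solve the weight ratio
    albumin = ifelse(.data$cachectic, cach_albumin,
                     (unname(a$nri[.data$nri_class]) - coef_ratio) / coef_alb),
    weight_ratio = ifelse(
      .data$cachectic,
      (unname(a$nri[.data$nri_class]) - coef_alb * cach_albumin) / coef_ratio,
      1),
    usual_weight = .data$current_weight / .data$weight_ratio,
    crp = ifelse(.data$cachectic, 20, 2),
    transferrin = ifelse(.data$cachectic, 100, 250),
    hand_grip = unname(ifelse(.data$sarcopenia == "none",
                              a$grip_ok[.data$gender],
                              a$grip_low[.data$gender])),
    gait_speed = ifelse(.data$sarcopenia == "severe", 0.5, 1.0),
    asmm_target = unname(ifelse(.data$sarcopenia %in% c("diagnosed", "severe"),
                                a$asmm_low[.data$gender],
                                a$asmm_ok[.data$gender])),
    reactance = 50,
    resistance = solve_resistance(.data$asmm_target, .data$current_weight,
                                  .data$gender, .data$reactance, .data$height)
  )

  tibble::tibble(
    id = sprintf("A%04d", seq_len(nrow(out))),
    gender = out$gender,
    age = out$age,
    current_weight = out$current_weight,
    usual_weight = out$usual_weight,
    height = out$height,
    fev1_percent = out$fev1_percent,
    hand_grip = out$hand_grip,
    gait_speed = out$gait_speed,
    resistance = out$resistance,
    reactance = out$reactance,
    albumin = out$albumin,
    crp = out$crp,
    transferrin = out$transferrin,
    pco2 = NA_real_,
    has_t2dm = FALSE,
    has_hypercholesterolemia = FALSE,
    target_phenotype = out$phenotype,
    target_stage = out$stage,
    target_nri_class = out$nri_class,
    target_sarcopenia = out$sarcopenia,
    target_cachectic = out$cachectic
  )
}

#' Boundary patients at every published cutoff
#'
#' For every cutoff in the rule base, two patients: one exactly at the cutoff
#' and one a single display decimal away on the other side (0.1 for FEV1,
#' grip, BMI, NRI, CRP and transferrin; 0.01 for gait speed and albumin).
#' Engineered quantities (BMI, NRI, ASMM) are constructed by inverting the
#' corresponding equation and verified to land on the intended side.
#'
#' @return tibble of patient inputs plus `case` (cutoff being probed),
#'   `label_field` (which classification output the pair separates) and
#'   `expected` (label or flag expected from classification).
#' @examples
#' b <- generate_boundary_cases()
#' table(b$case)
#' @export
generate_boundary_cases <- function() {
  base_m <- baseline_patient("male")
  base_f <- baseline_patient("female")

  mk <- function(base, case, field, value, label_field, expected) {
    p <- base
    p[[field]] <- value
    p$case <- case
    p$label_field <- label_field
    p$expected <- as.character(expected)
    p
  }
  h2 <- function(g) ARCHETYPE_ANCHORS$height[[g]]^2

  rows <- list(
    mk(base_m, "fev1_80", "fev1_percent", 80, "copd_stage", "I"),
    mk(base_m, "fev1_80", "fev1_percent", 79.9, "copd_stage", "II"),
    mk(base_m, "fev1_50", "fev1_percent", 50, "copd_stage", "II"),
    mk(base_m, "fev1_50", "fev1_percent", 49.9, "copd_stage", "III"),
    mk(base_m, "fev1_30", "fev1_percent", 30, "copd_stage", "III"),
    mk(base_m, "fev1_30", "fev1_percent", 29.9, "copd_stage", "IV"),

    mk(base_m, "bmi_18.5", "current_weight", solve_weight(18.5, base_m$height),
       "phenotype", "normal_weight"),
    mk(base_m, "bmi_18.5", "current_weight", 18.4 * h2("male"),
       "phenotype", "underweight"),
    mk(base_m, "bmi_25", "current_weight", solve_weight(25, base_m$height),
       "phenotype", "overweight"),
    mk(base_m, "bmi_25", "current_weight", 24.9 * h2("male"),
       "phenotype", "normal_weight"),
    mk(base_m, "bmi_30", "current_weight", solve_weight(30, base_m$height),
       "phenotype", "obesity_1"),
    mk(base_m, "bmi_30", "current_weight", 29.9 * h2("male"),
       "phenotype", "overweight"),
    mk(base_m, "bmi_35", "current_weight", solve_weight(35, base_m$height),
       "phenotype", "obesity_2"),
    mk(base_m, "bmi_35", "current_weight", 34.9 * h2("male"),
       "phenotype", "obesity_1"),
    mk(base_m, "bmi_40", "current_weight", solve_weight(40, base_m$height),
       "phenotype", "obesity_3"),
    mk(base_m, "bmi_40", "current_weight", 39.9 * h2("male"),
       "phenotype", "obesity_2"),

    mk(base_m, "grip_27_male", "hand_grip", 27, "sarcopenia_level", "none"),
    mk(base_m, "grip_27_male", "hand_grip", 26.9, "sarcopenia_level", "probable"),
    mk(base_f, "grip_16_female", "hand_grip", 16, "sarcopenia_level", "none"),
    mk(base_f, "grip_16_female", "hand_grip", 15.9, "sarcopenia_level", "probable"),

    mk(base_m, "nri_100", "albumin", solve_albumin_for_nri(100),
       "nri_class", "mild"),
    mk(base_m, "nri_100", "albumin", solve_albumin_for_nri(100.1),
       "nri_class", "absence"),
    mk(base_m, "nri_97.5", "albumin", solve_albumin_for_nri(97.5),
       "nri_class", "mild"),
    mk(base_m, "nri_97.5", "albumin", solve_albumin_for_nri(97.4),
       "nri_class", "moderate"),
    mk(base_m, "nri_83.5", "albumin", solve_albumin_for_nri(83.5),
       "nri_class", "moderate"),
    mk(base_m, "nri_83.5", "albumin", solve_albumin_for_nri(83.4),
       "nri_class", "severe")
  )

  # low-muscle-quantity cutoffs: absolute ASMM probed at a height where the
  # ASMM/height^2 branch stays silent, and vice versa
  asmm_pair <- function(gender, case, height, asmm_at, asmm_off) {
    b <- baseline_patient(gender)
    b$height <- height
    b$current_weight <- 21.7 * height^2 # keep normal weight
    b$hand_grip <- ARCHETYPE_ANCHORS$grip_low[[gender]] # criterion 1 met
    at <- b; off <- b
    at$resistance <- solve_resistance(asmm_at, at$current_weight, gender,
                                      at$reactance, height)
    off$resistance <- solve_resistance(asmm_off, off$current_weight, gender,
                                       off$reactance, height) * (1 + 2^-40)
    at$case <- case; off$case <- case
    at$label_field <- "sarcopenia_level"; off$label_field <- "sarcopenia_level"
    at$expected <- "probable"; off$expected <- "diagnosed"
    list(at, off)
  }
  rows <- c(
    rows,
    asmm_pair("male", "asmm_20_male", 1.60, 20, 19.9),
    asmm_pair("male", "asmm_h2_7_male", 1.75, 7 * 1.75^2, 6.9 * 1.75^2),
    asmm_pair("female", "asmm_15_female", 1.62, 15, 14.9),
    asmm_pair("female", "asmm_h2_5.5_female", 1.70, 5.5 * 1.70^2, 5.4 * 1.70^2)
  )

  # gait speed: criteria 1 and 2 held true so only criterion 3 separates
  gait_base <- baseline_patient("male")
  gait_base$hand_grip <- 20
  gait_base$resistance <- solve_resistance(15, gait_base$current_weight,
                                           "male", gait_base$reactance,
                                           gait_base$height) * (1 + 2^-40)
  rows <- c(rows, list(
    mk(gait_base, "gait_0.8", "gait_speed", 0.8, "sarcopenia_level", "severe"),
    mk(gait_base, "gait_0.8", "gait_speed", 0.81, "sarcopenia_level", "diagnosed")
  ))

  # cachexia triad: sarcopenic baseline with two of three criteria met
  cach_base <- gait_base
  cach_base$gait_speed <- 1.0
  cach_base$albumin <- 3.0
  cach_base$crp <- 20
  cach_base$transferrin <- 100
  vary <- function(field, at, off, case) {
    list(mk(cach_base, case, field, at, "cachectic", "FALSE"),
         mk(cach_base, case, field, off, "cachectic", "TRUE"))
  }
  rows <- c(rows,
            vary("crp", 10, 10.1, "crp_10"),
            vary("transferrin", 150, 149.9, "transferrin_150"),
            vary("albumin", 3.5, 3.49, "albumin_3.5"))

  out <- dplyr::bind_rows(rows)
  out$id <- sprintf("B%03d", seq_len(nrow(out)))
  dplyr::select(out, "id", dplyr::everything())
}

baseline_patient <- function(gender) {
  h <- ARCHETYPE_ANCHORS$height[[gender]]
  w <- 21.7 * h^2
  tibble::tibble(
    id = "B000", gender = gender, age = 65,
    current_weight = w, usual_weight = w, height = h,
    fev1_percent = 65,
    hand_grip = ARCHETYPE_ANCHORS$grip_ok[[gender]],
    gait_speed = 1.0,
    resistance = solve_resistance(ARCHETYPE_ANCHORS$asmm_ok[[gender]], w,
                                  gender, 50, h),
    reactance = 50,
    albumin = 4.2, crp = 2, transferrin = 250,
    pco2 = NA_real_, has_t2dm = FALSE, has_hypercholesterolemia = FALSE
  )
}

# weight whose recomputed BMI is >= bmi_target (guards the half-open interval)
solve_weight <- function(bmi_target, height) {
  w <- bmi_target * height^2
  for (k in 1:5) {
    if (compute_bmi(w, height) >= bmi_target) break
    w <- w * (1 + 2^-50)
  }
  w
}

#' Generate a synthetic patient cohort
#'
#' Three coverage modes. `"random"` draws `n` seeded patients from plausible
#' clinical ranges (age 40-90, FEV1 15-110%, BMI 14-42 kg/m^2, albumin
#' 2.5-5 g/dL, ...); the ranges make cohorts clinically sensible but do not
#' model any population. `"lattice"` returns the archetype set (every
#' reachable classification at least once; `n` and `seed` are ignored).
#' `"boundary"` returns the cutoff boundary set (`n` and `seed` ignored).
#' All generated patients pass [validate_patients()]; the same spec always
#' yields the identical cohort.
#'
#' @param n number of patients (random mode).
#' @param seed integer seed (random mode).
#' @param coverage "random", "lattice" or "boundary".
#' @return tibble of patient inputs.
#' @examples
#' generate_cohort(5, seed = 1)
#' @export
generate_cohort <- function(n = 100, seed = 1, coverage = c("random", "lattice",
                                                            "boundary")) {
  coverage <- match.arg(coverage)
  if (coverage == "lattice") {
    return(dplyr::select(generate_archetypes(),
                         -dplyr::starts_with("target_")))
  }
  if (coverage == "boundary") {
    return(dplyr::select(generate_boundary_cases(),
                         -dplyr::all_of(c("case", "label_field", "expected"))))
  }
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n < 1) {
    abort("`n` must be a positive integer")
  }
  n <- as.integer(n)
  with_preserved_rng({
    set.seed(seed)
    gender <- sample(GENDER_LEVELS, n, replace = TRUE)
    height <- round(ifelse(gender == "male", stats::runif(n, 1.60, 1.90),
                           stats::runif(n, 1.50, 1.80)), 2)
    bmi <- stats::runif(n, 14, 42)
    weight <- round(bmi * height^2, 1)
    ratio <- stats::runif(n, 0.85, 1.2)
    tibble::tibble(
      id = sprintf("S%04d", seq_len(n)),
      gender = gender,
      age = sample(40:90, n, replace = TRUE),
      current_weight = weight,
      usual_weight = round(weight / ratio, 1),
      height = height,
      fev1_percent = round(stats::runif(n, 15, 110), 1),
      hand_grip = round(ifelse(gender == "male", stats::runif(n, 15, 55),
                               stats::runif(n, 8, 40)), 1),
      gait_speed = round(stats::runif(n, 0.3, 1.5), 2),
      resistance = round(stats::runif(n, 350, 800)),
      reactance = round(stats::runif(n, 30, 70)),
      albumin = round(stats::runif(n, 2.5, 5), 2),
      crp = round(stats::runif(n, 0, 30), 1),
      transferrin = round(stats::runif(n, 100, 350)),
      pco2 = ifelse(stats::runif(n) < 0.3, round(stats::runif(n, 35, 60)),
                    NA_real_),
      has_t2dm = stats::runif(n) < 0.15,
      has_hypercholesterolemia = stats::runif(n) < 0.15
    )
  })
}

with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
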