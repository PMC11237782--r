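test_that("BMI arithmetic and preconditions", {
  expect_equal(compute_bmi(70, 1.75), 70 / 3.0625)
  expect_equal(compute_bmi(25, 1.0), 25)
  expect_error(compute_bmi(0, 1.7), "weight")
  expect_error(compute_bmi(70, 0), "height")
})

test_that("phenotype cutoffs follow the half-open WHO intervals", {
  expect_equal(as.character(classify_phenotype(18.5)), "normal_weight")
  expect_equal(as.character(classify_phenotype(18.49)), "underweight")
  expect_equal(as.character(classify_phenotype(24.95)), "normal_weight")
  expect_equal(as.character(classify_phenotype(25.0)), "overweight")
  expect_equal(as.character(classify_phenotype(30.0)), "obesity_1")
  expect_warning(p3 <- classify_phenotype(42), "degree-II")
  expect_equal(as.character(p3), "obesity_3")
})

test_that("COPD staging follows the FEV1 cutoffs", {
  expect_equal(as.character(stage_copd(c(80, 79.9, 50, 49.9, 30, 29.9))),
               c("I", "II", "II", "III", "III", "IV"))
  expect_error(stage_copd(0), "fev1")
})

test_that("NRI formula with g/dL -> g/L conversion", {
  expect_equal(compute_nri(4.0, 60, 60), 102.46)
  expect_equal(compute_nri(3.0, 54, 60), 83.10)
  # formula limit: albumin term vanishes, ratio term remains
  expect_equal(compute_nri(1e-9, 54, 60), 41.7 * 0.9, tolerance = 1e-6)
  expect_error(compute_nri(4, 60, 0), "usual_weight")
})

test_that("NRI classes: absence >100, mild [97.5,100], moderate [83.5,97.5), severe <83.5", {
  expect_equal(as.character(classify_nri(c(100.0, 100.1, 97.5, 97.49, 83.5, 83.49))),
               c("mild", "absence", "mild", "moderate", "moderate", "severe"))
})

test_that("resistive index is height(cm)^2 over resistance", {
  expect_equal(compute_resistive_index(1.75, 500), 61.25)
  expect_equal(compute_resistive_index(1.0, 100), 100)
  expect_error(compute_resistive_index(1.6, 0), "resistance")
})

test_that("Sergi ASMM equation with male/female coding", {
  expect_equal(compute_asmm(61.25, 70, "male", 50), 21.17375)
  expect_equal(compute_asmm(61.25, 70, "female", 50), 19.78975)
  expect_warning(low <- compute_asmm(1e-6, 1e-6, "female", 0), "implausibly")
  expect_equal(low, -3.964, tolerance = 1e-4)
})

test_that("sarcopenia ladder combines the three criteria correctly", {
  # boundary: grip exactly at cutoff is NOT below it
  expect_equal(as.character(assess_sarcopenia("male", 27, 23, 1.75, 1.0)),
               "none")
  expect_equal(as.character(assess_sarcopenia("female", 15, 14, 1.62, 0.9)),
               "diagnosed")
  # criterion 2 is an OR: absolute ASMM fine but ASMM/h^2 below cutoff
  expect_equal(as.character(assess_sarcopenia("male", 20, 21, 1.75, 0.8)),
               "severe")
  expect_equal(as.character(assess_sarcopenia("male", 20, 23, 1.75, 0.5)),
               "probable") # criterion 3 without criterion 2 stays probable
})

test_that("cachexia needs the full triad plus sarcopenia", {
  expect_true(assess_cachexia(11, 140, 3.4, "diagnosed"))
  expect_false(assess_cachexia(11, 140, 3.4, "none"))
  expect_false(assess_cachexia(10, 140, 3.4, "severe"))   # 10 is not > 10
  expect_false(assess_cachexia(11, 150, 3.4, "severe"))
  expect_false(assess_cachexia(11, 140, 3.5, "severe"))
})

test_that("interval classifiers agree with the nested-conditional oracle", {
  x <- random_classification_inputs(100000, seed = 101)
  ph <- suppressWarnings(classify_phenotype(x$bmi)) # BMI >= 40 warns by design
  expect_equal(as.character(ph),
               vapply(x$bmi, oracle_phenotype, character(1)))
  expect_equal(as.character(stage_copd(x$fev1)),
               vapply(x$fev1, oracle_stage, character(1)))
  expect_equal(as.character(classify_nri(x$nri)),
               vapply(x$nri, oracle_nri_class, character(1)))
})

test_that("sarcopenia ladder agrees with the oracle and is monotone", {
  x <- random_classification_inputs(20000, seed = 202)
  got <- as.character(assess_sarcopenia(x$gender, x$grip, x$asmm, x$height,
                                        x$gait))
  want <- mapply(oracle_sarcopenia, x$gender, x$grip, x$asmm, x$height,
                 x$gait)
  expect_equal(got, unname(want))
  # ladder: severe satisfies the diagnosed criteria, diagnosed the probable
  sev <- x[got == "severe", ]
  if (nrow(sev) > 0) {
    relaxed <- as.character(assess_sarcopenia(sev$gender, sev$grip, sev$asmm,
                                              sev$height, 1.0))
    expect_true(all(relaxed == "diagnosed"))
  }
})

test_that("classification is total: exactly one label per dimension", {
  x <- random_classification_inputs(100000, seed = 303)
  expect_false(anyNA(suppressWarnings(classify_phenotype(x$bmi))))
  expect_false(anyNA(stage_copd(x$fev1)))
  expect_false(anyNA(classify_nri(x$nri)))
  expect_false(anyNA(assess_sarcopenia(x$gender, x$grip, x$asmm, x$height,
                                       x$gait)))
})

test_that("NRI is strictly increasing in albumin and weight ratio; ASMM in its inputs", {
  a <- seq(2, 5, by = 0.1)
  expect_true(all(diff(compute_nri(a, 60, 60)) > 0))
  w <- seq(40, 80, by = 1)
  expect_true(all(diff(compute_nri(3.5, w, 60)) > 0))
  ri <- seq(20, 90, by = 1)
  expect_true(all(diff(compute_asmm(ri, 70, "male", 50)) > 0))
  expect_true(all(diff(compute_asmm(60, w, "female", 50)) > 0))
  xc <- seq(30, 70, by = 1)
  expect_true(all(diff(compute_asmm(60, 70, "male", xc)) > 0))
})

test_that("classify_patients fills every field and traces every rule family", {
  cls <- classify_patients(worked_patient())
  expect_equal(as.character(cls$phenotype), "normal_weight")
  expect_equal(as.character(cls$copd_stage), "II")
  expect_equal(as.character(cls$nri_class), "absence")
  expect_equal(as.character(cls$sarcopenia_level), "none")
  expect_false(cls$cachectic)
  tr <- attr(cls, "trace")
  expect_setequal(
    unique(tr$rule_id),
    c("CLS-BMI", "CLS-STAGE", "CLS-NRI-EQ", "CLS-NRI-CLASS", "CLS-ASMM-EQ",
      "CLS-SARC", "CLS-CACHEXIA"))
  cls_fields <- c("bmi", "phenotype", "copd_stage", "nri_value", "nri_class",
                  "resistive_index", "asmm", "sarcopenia_level", "cachectic")
  expect_true(all(cls_fields %in% tr$field))
})
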