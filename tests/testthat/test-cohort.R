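test_that("archetype inversion round-trips every reachable combination", {
  arch <- generate_archetypes()
  # 2 genders x 5 phenotypes x 4 stages x 4 NRI classes x 7 status combos
  expect_equal(nrow(arch), 2 * 5 * 4 * 4 * 7)
  # cachexia without sarcopenia is never generated
  expect_false(any(arch$target_cachectic & arch$target_sarcopenia == "none"))
  cls <- classify_patients(arch)
  expect_equal(as.character(cls$phenotype), arch$target_phenotype)
  expect_equal(as.character(cls$copd_stage), arch$target_stage)
  expect_equal(as.character(cls$nri_class), arch$target_nri_class)
  expect_equal(as.character(cls$sarcopenia_level), arch$target_sarcopenia)
  expect_equal(cls$cachectic, arch$target_cachectic)
})

test_that("archetypes include the reference label patterns", {
  arch <- generate_archetypes()
  # underweight / stage I / severe risk / cachectic (severe sarcopenia)
  expect_true(any(arch$target_phenotype == "underweight" &
                    arch$target_stage == "I" &
                    arch$target_nri_class == "severe" &
                    arch$target_sarcopenia == "severe" &
                    arch$target_cachectic))
  # normal weight / stage IV / absence of risk / no sarcopenia
  expect_true(any(arch$target_phenotype == "normal_weight" &
                    arch$target_stage == "IV" &
                    arch$target_nri_class == "absence" &
                    arch$target_sarcopenia == "none" &
                    !arch$target_cachectic))
  # obesity degree I / stage III / mild risk / non-sarcopenic
  expect_true(any(arch$target_phenotype == "obesity_1" &
                    arch$target_stage == "III" &
                    arch$target_nri_class == "mild" &
                    arch$target_sarcopenia == "none"))
})

test_that("boundary patients split every cutoff at display precision", {
  b <- generate_boundary_cases()
  cls <- suppressWarnings(classify_patients(b))
  got <- vapply(seq_len(nrow(cls)),
                function(i) as.character(cls[[cls$label_field[i]]][i]),
                character(1))
  expect_equal(got, cls$expected)
  # each probed cutoff contributes both sides
  expect_true(all(table(b$case) == 2))
})

test_that("random cohorts are seeded, reproducible and valid", {
  c1 <- generate_cohort(100, seed = 1)
  c2 <- generate_cohort(100, seed = 1)
  expect_identical(c1, c2)
  c3 <- generate_cohort(100, seed = 2)
  expect_false(identical(c1, c3))
  # closed under validation
  expect_silent(v <- validate_patients(generate_cohort(1000, seed = 2)))
  expect_equal(nrow(v), 1000)
  expect_error(generate_cohort(0), "positive")
})

test_that("cohort generation does not disturb the global RNG stream", {
  set.seed(42)
  before <- runif(1)
  set.seed(42)
  invisible(generate_cohort(10, seed = 7))
  expect_identical(runif(1), before)
})

test_that("lattice coverage reaches every classification at least once", {
  lat <- generate_cohort(coverage = "lattice")
  cls <- classify_patients(lat)
  combos <- unique(paste(cls$phenotype, cls$copd_stage, cls$nri_class,
                         cls$sarcopenia_level, cls$cachectic))
  expect_equal(length(combos), 5 * 4 * 4 * 7)
})
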