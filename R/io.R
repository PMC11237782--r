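PATIENT_COLUMNS <- c("id", "gender", "age", "current_weight", "usual_weight",
                     "height", "fev1_percent", "hand_grip", "gait_speed",
                     "resistance", "reactance", "albumin", "crp",
                     "transferrin", "pco2", "has_t2dm",
                     "has_hypercholesterolemia")

#' Read patients from CSV or JSON
#'
#' Strict schema reader: the file must contain only documented patient
#' columns (mandatory columns of [validate_patients()] plus the optional
#' `usual_weight`, `pco2`, `has_t2dm`, `has_hypercholesterolemia`). Records
#' are validated; errors name the offending row and field.
#'
#' @param path file path.
#' @param format "csv", "json", or "auto" (by file extension).
#' @return validated patient tibble.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_patients(generate_cohort(3, seed = 1), f)
#' read_patients(f)
#' @export
read_patients <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  raw <- if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::as_tibble(jsonlite::fromJSON(path))
  }
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    warn("empty patient file")
    return(suppressWarnings(validate_patients(empty_patient_table())))
  }
  unknown <- setdiff(names(raw), PATIENT_COLUMNS)
  if (length(unknown) > 0) {
    abort(paste0("unknown column(s) in ", path, ": ",
                 paste(unknown, collapse = ", ")))
  }
  validate_patients(raw)
}

empty_patient_table <- function() {
  tibble::tibble(
    id = character(), gender = character(), age = numeric(),
    current_weight = numeric(), usual_weight = numeric(), height = numeric(),
    fev1_percent = numeric(), hand_grip = numeric(), gait_speed = numeric(),
    resistance = numeric(), reactance = numeric(), albumin = numeric(),
    crp = numeric(), transferrin = numeric(), pco2 = numeric(),
    has_t2dm = logical(), has_hypercholesterolemia = logical()
  )
}

#' Write patients to CSV or JSON
#'
#' Writes the documented patient schema (comma-separated, UTF-8, header row,
#' decimal point) so that a write/read round trip reproduces the cohort
#' exactly.
#'
#' @param data patient tibble.
#' @param path output file path.
#' @param format "csv", "json", or "auto" (by file extension).
#' @return `path`, invisibly.
#' @export
write_patients <- function(data, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  data <- validate_patients(data)[, PATIENT_COLUMNS]
  if (format == "csv") {
    readr::write_csv(data, path, progress = FALSE)
  } else {
    jsonlite::write_json(data, path, auto_unbox = FALSE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Write an assessment report
#'
#' Deterministic serialization of classification, recommendation and rule
#' trace for every patient, mirroring the three panels a clinician sees:
#' patient profile, health condition, nutritional recommendations. Every
#' value is annotated (via the rules section) with the provenance of the rule
#' that produced it, so guideline constants and package assumptions are
#' distinguishable.
#'
#' @param assessment a `copd_assessment` from [assess_patients()].
#' @param format "json" or "markdown".
#' @param path optional output file.
#' @return the report as a single character scalar, invisibly if `path` is
#'   given.
#' @examples
#' a <- generate_cohort(1, seed = 3) |> assess_patients()
#' cat(write_report(a, format = "markdown"))
#' @export
write_report <- function(assessment, format = c("json", "markdown"),
                         path = NULL) {
  format <- match.arg(format)
  needed <- c("phenotype", "bmr_kcal")
  if (!all(needed %in% names(assessment))) {
    abort("`assessment` must come from assess_patients()")
  }
  trace <- rule_trace(assessment)
  r2 <- function(x) round_half_up(x, 2)
  r1 <- function(x) round_half_up(x, 1)

  patient_block <- function(i) {
    p <- assessment[i, ]
    tr <- trace[trace$id == p$id, ]
    rules <- unique(tr[, c("rule_id", "description", "provenance")])
    rules <- rules[order(rules$rule_id), ]
    rule_list <- purrr::pmap(rules, function(rule_id, description, provenance) {
      list(rule_id = rule_id, description = description,
           provenance = provenance,
           fields = sort(unique(tr$field[tr$rule_id == rule_id])))
    })
    list(
      id = p$id,
      profile = list(
        gender = p$gender, age = p$age, current_weight_kg = p$current_weight,
        usual_weight_kg = p$usual_weight, height_m = p$height,
        fev1_percent = p$fev1_percent, hand_grip_kg = p$hand_grip,
        gait_speed_m_s = p$gait_speed, resistance_ohm = p$resistance,
        reactance_ohm = p$reactance, albumin_g_dl = p$albumin,
        crp_mg_l = p$crp, transferrin_mg_dl = p$transferrin,
        pco2_mm_hg = p$pco2, has_t2dm = p$has_t2dm,
        has_hypercholesterolemia = p$has_hypercholesterolemia
      ),
      health_condition = list(
        bmi = r2(p$bmi), phenotype = as.character(p$phenotype),
        copd_stage = as.character(p$copd_stage),
        nri_value = r2(p$nri_value), nri_class = as.character(p$nri_class),
        resistive_index = r2(p$resistive_index), asmm_kg = r2(p$asmm),
        sarcopenia_level = as.character(p$sarcopenia_level),
        cachectic = p$cachectic
      ),
      nutritional_recommendation = list(
        bmr_kcal = p$bmr_kcal, energy_factor = p$energy_factor,
        energy_kcal = p$energy_kcal, meals_per_day = p$meals_per_day,
        energy_protein_supplement = p$energy_protein_supplement,
        bcaa_supplement = p$bcaa_supplement,
        protein_share_pct = r1(p$protein_share), protein_g = p$protein_g,
        carb_share_pct = c(p$carb_share_min, p$carb_share_max),
        carb_g = c(p$carb_g_min, p$carb_g_max),
        fat_share_pct = c(r1(p$fat_share_min), r1(p$fat_share_max)),
        fat_g = c(p$fat_g_min, p$fat_g_max),
        sugar_share_max_pct = p$sugar_share_max, sugar_g_max = p$sugar_g_max,
        satfat_share_max_pct = p$satfat_share_max,
        satfat_g_max = p$satfat_g_max,
        cholesterol_max_mg = p$cholesterol_max_mg,
        fiber_g = c(p$fiber_min_g, p$fiber_max_g),
        sodium_max_mg = p$sodium_max_mg, calcium_mg = p$calcium_mg
      ),
      rules = rule_list
    )
  }
  blocks <- purrr::map(seq_len(nrow(assessment)), patient_block)

  out <- if (format == "json") {
    jsonlite::toJSON(list(patients = blocks), auto_unbox = TRUE, digits = NA,
                     pretty = TRUE, na = "null")
  } else {
    paste(purrr::map_chr(blocks, markdown_block), collapse = "\n")
  }
  out <- as.character(out)
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

markdown_block <- function(b) {
  fmt <- function(x) {
    if (is.logical(x)) return(ifelse(x, "yes", "no"))
    if (length(x) == 2) return(paste0(x[1], "-", x[2]))
    as.character(x)
  }
  hc <- b$health_condition
  rec <- b$nutritional_recommendation
  assumed <- purrr::keep(b$rules, ~ .x$provenance == "assumption")
  paste0(
    "# Patient ", b$id, "\n\n",
    "## Health condition\n\n",
    "- BMI: ", hc$bmi, " kg/m2 (", hc$phenotype, ")\n",
    "- COPD stage: ", hc$copd_stage, "\n",
    "- NRI: ", hc$nri_value, " (", hc$nri_class, " risk class)\n",
    "- ASMM: ", hc$asmm_kg, " kg (resistive index ", hc$resistive_index, ")\n",
    "- Sarcopenia: ", hc$sarcopenia_level, "\n",
    "- Cachectic: ", fmt(hc$cachectic), "\n\n",
    "## Nutritional recommendations\n\n",
    "- Basal metabolic rate: ", rec$bmr_kcal, " kcal/day\n",
    "- Total daily energy (x", rec$energy_factor, "): ", rec$energy_kcal,
    " kcal/day\n",
    "- Meals per day: ", rec$meals_per_day, "\n",
    "- Energy-protein supplement: ", fmt(rec$energy_protein_supplement), "\n",
    "- BCAA supplement: ", fmt(rec$bcaa_supplement), "\n",
    "- Protein: ", rec$protein_share_pct, "% / ", rec$protein_g, " g\n",
    "- Carbohydrate: ", fmt(rec$carb_share_pct), "% / ", fmt(rec$carb_g), " g\n",
    "- Fat: ", fmt(rec$fat_share_pct), "% / ", fmt(rec$fat_g), " g\n",
    "- Sugar (max): ", rec$sugar_share_max_pct, "% / ", rec$sugar_g_max, " g\n",
    "- Saturated fat (max): ", rec$satfat_share_max_pct, "% / ",
    rec$satfat_g_max, " g\n",
    "- Cholesterol (max): ", rec$cholesterol_max_mg, " mg\n",
    "- Fiber: ", fmt(rec$fiber_g), " g\n",
    "- Sodium (max): ", rec$sodium_max_mg, " mg\n",
    "- Calcium: ", rec$calcium_mg, " mg\n\n",
    "## Assumption-based values\n\n",
    if (length(assumed) == 0) "(none)\n" else paste0(
      purrr::map_chr(assumed, ~ paste0("- ", .x$rule_id, ": ",
                                       .x$description, "\n")),
      collapse = ""),
    "\n"
  )
}

#' Export an assessment as RDF Turtle
#'
#' Emits subject-predicate-object triples using the `copd:` vocabulary
#' (copd:isInHealthCondition, copd:hasRecommendation, copd:FEV1,
#' copd:nutritionalRiskIndex, copd:proteinsGrams,
#' copd:regularRecommendedCaloricIntake,
#' copd:correctedRecommendedCaloricIntake, ...). Each patient gets exactly
#' one health-condition individual and one recommendation individual.
#'
#' @param assessment a `copd_assessment` from [assess_patients()].
#' @param path optional output file.
#' @param base_iri IRI bound to the `copd:` prefix.
#' @return character vector of Turtle lines, invisibly if `path` is given.
#' @examples
#' a <- generate_cohort(1, seed = 3) |> assess_patients()
#' head(export_triples(a))
#' @export
export_triples <- function(assessment, path = NULL,
                           base_iri = "http://example.org/copd-nutrition#") {
  if (!all(c("phenotype", "bmr_kcal") %in% names(assessment))) {
    abort("`assessment` must come from assess_patients()")
  }
  lit <- function(x) {
    if (is.logical(x)) return(paste0('"', tolower(as.character(x)),
                                     '"^^xsd:boolean'))
    paste0('"', format(x, scientific = FALSE, trim = TRUE), '"^^xsd:decimal')
  }
  safe <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

  lines <- c(
    paste0("@prefix copd: <", base_iri, "> ."),
    "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
    ""
  )
  for (i in seq_len(nrow(assessment))) {
    p <- assessment[i, ]
    sid <- safe(p$id)
    pat <- paste0("copd:Patient_", sid)
    hc <- paste0("copd:HC_", sid)
    rec <- paste0("copd:Rec_", sid)
    lines <- c(
      lines,
      paste0(pat, " a copd:Patient , copd:",
             ifelse(p$gender == "male", "Male", "Female"), " ;"),
      paste0("    copd:patientID ", '"', p$id, '" ;'),
      paste0("    copd:isInHealthCondition ", hc, " ;"),
      paste0("    copd:hasRecommendation ", rec, " ."),
      paste0(hc, " a copd:Health_Condition ;"),
      paste0("    copd:age ", lit(p$age), " ;"),
      paste0("    copd:currentWeight ", lit(p$current_weight), " ;"),
      paste0("    copd:usualWeight ", lit(p$usual_weight), " ;"),
      paste0("    copd:height_meters ", lit(p$height), " ;"),
      paste0("    copd:FEV1 ", lit(p$fev1_percent), " ;"),
      paste0("    copd:handGrip ", lit(p$hand_grip), " ;"),
      paste0("    copd:gaitSpeed ", lit(p$gait_speed), " ;"),
      paste0("    copd:resistance ", lit(p$resistance), " ;"),
      paste0("    copd:reactance ", lit(p$reactance), " ;"),
      paste0("    copd:albuminemia ", lit(p$albumin), " ;"),
      paste0("    copd:PCR ", lit(p$crp), " ;"),
      paste0("    copd:ironTransport ", lit(p$transferrin), " ;"),
      paste0("    copd:resistiveIndex ", lit(round_half_up(p$resistive_index, 2)), " ;"),
      paste0("    copd:appendicularSkeletalMuscleMass ",
             lit(round_half_up(p$asmm, 2)), " ;"),
      paste0("    copd:nutritionalRiskIndex ",
             lit(round_half_up(p$nri_value, 2)), " ."),
      paste0(rec, " a copd:Nutritional_Recommendation ;"),
      paste0("    copd:regularRecommendedCaloricIntake ", lit(p$bmr_kcal), " ;"),
      paste0("    copd:correctedRecommendedCaloricIntake ", lit(p$energy_kcal), " ;"),
      paste0("    copd:proteinsGrams ", lit(p$protein_g), " ;"),
      paste0("    copd:proteinShare ", lit(round_half_up(p$protein_share, 1)), " ;"),
      paste0("    copd:carbohydratesMINshare ", lit(p$carb_share_min), " ;"),
      paste0("    copd:carbohydratesMAXshare ", lit(p$carb_share_max), " ;"),
      paste0("    copd:fatsMINshare ", lit(round_half_up(p$fat_share_min, 1)), " ;"),
      paste0("    copd:fatsMAXshare ", lit(round_half_up(p$fat_share_max, 1)), " ;"),
      paste0("    copd:sugarMAXshare ", lit(p$sugar_share_max), " ;"),
      paste0("    copd:saturatedFatsMAXshare ", lit(p$satfat_share_max), " ;"),
      paste0("    copd:cholesterolMAXamount ", lit(p$cholesterol_max_mg), " ;"),
      paste0("    copd:fiberMINamount ", lit(p$fiber_min_g), " ;"),
      paste0("    copd:fiberMAXamount ", lit(p$fiber_max_g), " ;"),
      paste0("    copd:sodiumMAXamount ", lit(p$sodium_max_mg), " ;"),
      paste0("    copd:calciumAmount ", lit(p$calcium_mg), " ;"),
      paste0("    copd:mealsPerDay ", lit(p$meals_per_day), " ;"),
      paste0("    copd:BCAAsupplementation ", lit(p$bcaa_supplement), " ;"),
      paste0("    copd:energyProteinSupplementation ",
             lit(p$energy_protein_supplement), " ."),
      ""
    )
  }
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

#' Summarize expert agreement scores
#'
#' Per-item mean and sample (n-1) standard deviation of 1-5 Likert agreement
#' scores, plus the overall mean and sample SD of the item means. Rounding is
#' half-up to two decimals.
#'
#' @param scores data frame whose first column is the item label and whose
#'   remaining columns are integer scores in 1..5 (one column per rater), as
#'   returned by [agreement_scores()].
#' @return list with `items` (tibble: `item`, `n_raters`, `mean`, `sd`,
#'   `min`, `max`) and `overall` (tibble: `n_items`, `mean`, `sd`).
#' @examples
#' summarize_agreement(agreement_scores("validation"))
#' @export
summarize_agreement <- function(scores) {
  if (!is.data.frame(scores) || ncol(scores) < 2 || nrow(scores) == 0) {
    abort("`scores` must be a non-empty data frame: item column + score columns")
  }
  items <- as.character(scores[[1]])
  m <- as.matrix(scores[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  if (any(is.na(m)) || any(m != floor(m)) || any(m < 1) || any(m > 5)) {
    abort("scores must be integers between 1 and 5")
  }
  means <- rowMeans(m)
  sds <- apply(m, 1, stats::sd)
  out_items <- tibble::tibble(
    item = items,
    n_raters = ncol(m),
    mean = round_half_up(means, 2),
    sd = round_half_up(sds, 2),
    min = apply(m, 1, min),
    max = apply(m, 1, max)
  )
  overall <- tibble::tibble(
    n_items = length(means),
    mean = round_half_up(mean(means), 2),
    sd = if (length(means) > 1) round_half_up(stats::sd(means), 2) else NA_real_
  )
  list(items = out_items, overall = overall)
}

#' Bundled expert-panel agreement scores
#'
#' Two small score tables from the system's expert evaluation: `"validation"`
#' holds the 1-5 agreement of 7 dieticians with the recommendations generated
#' for 5 patient profiles (BB, FG, LA, TM, XY2); `"acceptability"` holds the
#' technology-acceptance ratings of 7 lung specialists (intention to use INT,
#' perceived usefulness PU1/PU2).
#'
#' @param which "validation" or "acceptability".
#' @return tibble with an `item` column and one integer column per rater.
#' @examples
#' agreement_scores("validation")
#' @export
agreement_scores <- function(which = c("validation", "acceptability")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0(which, "_agreement.csv"),
                   package = "nutricopd")
  readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
}
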