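#' Validate raw patient records
#'
#' Checks a data frame of raw assessment values against the patient input
#' schema and returns a validated tibble with normalized types. One row per
#' patient; columns are the full datatype-property set of a patient's health
#' condition plus demographics and comorbidity flags.
#'
#' Mandatory columns: `id`, `gender` ("male"/"female"), `age` (years),
#' `current_weight` (kg), `height` (m), `fev1_percent` (% of predicted),
#' `hand_grip` (kg), `gait_speed` (m/s), `resistance` (ohm), `reactance`
#' (ohm), `albumin` (g/dL), `crp` (mg/L), `transferrin` (mg/dL).
#' Optional: `usual_weight` (kg; defaults to `current_weight`, i.e. a neutral
#' weight ratio of 1), `pco2` (mm Hg; absent is treated as normocapnic),
#' `has_t2dm`, `has_hypercholesterolemia` (default `FALSE`).
#'
#' Heights above 3 m are rejected as probable centimetre input. Validation is
#' idempotent: validating an already-validated tibble returns it unchanged.
#'
#' @param data data frame of raw patient records.
#' @return A validated tibble, one row per patient.
#' @examples
#' p <- tibble::tibble(
#'   id = "P1", gender = "male", age = 64, current_weight = 70,
#'   usual_weight = 70, height = 1.75, fev1_percent = 65, hand_grip = 35,
#'   gait_speed = 1.1, resistance = 450, reactance = 50, albumin = 4.2,
#'   crp = 2, transferrin = 250
#' )
#' validate_patients(p)
#' @export
validate_patients <- function(data) {
  if (!is.data.frame(data)) abort("`data` must be a data frame of patient records")
  data <- tibble::as_tibble(data)

  mandatory <- c("id", "gender", "age", "current_weight", "height",
                 "fev1_percent", "hand_grip", "gait_speed", "resistance",
                 "reactance", "albumin", "crp", "transferrin")
  missing <- setdiff(mandatory, names(data))
  if (length(missing) > 0) {
    abort(paste0("missing mandatory patient field(s): ",
                 paste(missing, collapse = ", ")))
  }
  # columns beyond the schema (e.g. classification results, archetype targets)
  # are carried through untouched; strict schema checks live in read_patients()
  if (nrow(data) == 0) {
    warn("empty patient table")
  }
  if ("activity_level" %in% names(data)) {
    # deliberately not used: activity was judged marginal in this population
    inform(paste("`activity_level` supplied but the energy correction factors",
                 "do not use it; the column is carried through unchanged"))
  }

  out <- dplyr::mutate(
    data,
    id = as.character(.data$id),
    gender = as.character(.data$gender),
    age = as.numeric(.data$age),
    current_weight = as.numeric(.data$current_weight),
    usual_weight = if ("usual_weight" %in% names(data))
      dplyr::coalesce(as.numeric(.data$usual_weight), as.numeric(.data$current_weight))
      else as.numeric(.data$current_weight),
    height = as.numeric(.data$height),
    fev1_percent = as.numeric(.data$fev1_percent),
    hand_grip = as.numeric(.data$hand_grip),
    gait_speed = as.numeric(.data$gait_speed),
    resistance = as.numeric(.data$resistance),
    reactance = as.numeric(.data$reactance),
    albumin = as.numeric(.data$albumin),
    crp = as.numeric(.data$crp),
    transferrin = as.numeric(.data$transferrin),
    pco2 = if ("pco2" %in% names(data)) as.numeric(.data$pco2) else NA_real_,
    has_t2dm = if ("has_t2dm" %in% names(data))
      isTRUE_vec(.data$has_t2dm) else FALSE,
    has_hypercholesterolemia = if ("has_hypercholesterolemia" %in% names(data))
      isTRUE_vec(.data$has_hypercholesterolemia) else FALSE
  )

  problems <- collect_range_problems(out)
  if (nrow(problems) > 0) {
    msg <- paste0(
      "invalid patient value(s):\n",
      paste0("  row ", problems$row, " (id ", problems$id, "): ",
             problems$field, " ", problems$reason, collapse = "\n")
    )
    abort(msg, class = "nutricopd_validation_error")
  }

  if (anyDuplicated(out$id)) warn("duplicated patient ids")
  out
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(dplyr::coalesce(x, FALSE))
  if (is.numeric(x)) return(dplyr::coalesce(x != 0, FALSE))
  tolower(as.character(x)) %in% c("true", "t", "yes", "1")
}

collect_range_problems <- function(d) {
  checks <- list(
    list("gender", !d$gender %in% GENDER_LEVELS, "must be 'male' or 'female'"),
    list("age", !is.finite(d$age) | d$age <= 0 | d$age != floor(d$age),
         "must be a positive whole number of years"),
    list("current_weight", !is.finite(d$current_weight) | d$current_weight <= 0,
         "must be > 0 kg"),
    list("usual_weight", !is.finite(d$usual_weight) | d$usual_weight <= 0,
         "must be > 0 kg"),
    list("height", !is.finite(d$height) | d$height <= 0,
         "must be > 0 m"),
    list("height", is.finite(d$height) & d$height > 3,
         "looks like centimetres; expected metres"),
    list("fev1_percent", !is.finite(d$fev1_percent) | d$fev1_percent <= 0,
         "must be > 0 % of predicted"),
    list("hand_grip", !is.finite(d$hand_grip) | d$hand_grip < 0,
         "must be >= 0 kg"),
    list("gait_speed", !is.finite(d$gait_speed) | d$gait_speed < 0,
         "must be >= 0 m/s"),
    list("resistance", !is.finite(d$resistance) | d$resistance <= 0,
         "must be > 0 ohm"),
    list("reactance", !is.finite(d$reactance) | d$reactance < 0,
         "must be >= 0 ohm"),
    list("albumin", !is.finite(d$albumin) | d$albumin <= 0,
         "must be > 0 g/dL"),
    list("crp", !is.finite(d$crp) | d$crp < 0, "must be >= 0 mg/L"),
    list("transferrin", !is.finite(d$transferrin) | d$transferrin < 0,
         "must be >= 0 mg/dL"),
    list("pco2", !is.na(d$pco2) & (!is.finite(d$pco2) | d$pco2 <= 0),
         "must be > 0 mm Hg when present")
  )
  purrr::map_dfr(checks, function(ch) {
    bad <- which(ch[[2]])
    if (length(bad) == 0) return(tibble::tibble())
    tibble::tibble(row = bad, id = d$id[bad], field = ch[[1]], reason = ch[[3]])
  })
}
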