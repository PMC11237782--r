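#' The nutrition rule table
#'
#' Loads (and caches) the rule table that holds every cutoff and constant the
#' engine applies: classification cutoffs, the NRI and Sergi ASMM equation
#' coefficients, the Harris-Benedict / Mifflin-St Jeor BMR constants, the
#' 1.5/1.8 energy correction factors, and all nutrient rules. Each rule carries
#' a provenance flag: `"guideline"` for constants taken from the clinical rule
#' base, `"assumption"` where only a direction was stated and the package fixed
#' a conventional value. The table is a plain YAML file so clinicians can audit
#' or edit it without touching code.
#'
#' @param path optional path to an alternative YAML rule table. The default is
#'   the table shipped with the package.
#' @return A tibble with columns `id`, `description`, `condition`, `fields`
#'   (list column), `provenance` and `values` (list column of named numeric
#'   constants).
#' @examples
#' rules <- nutrition_rules()
#' rules[rules$id == "NUT-SODIUM", ]
#' @export
nutrition_rules <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.rules_cache$table)) return(.rules_cache$table)
    path <- system.file("extdata", "nutrient_rules.yaml", package = "nutricopd")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  raw <- yaml::read_yaml(path)
  tab <- purrr::map_dfr(raw$rules, function(r) {
    tibble::tibble(
      id = r$id,
      description = r$description,
      condition = r$condition %||% "",
      fields = list(unlist(r$fields)),
      provenance = r$provenance,
      values = list(r$values %||% list())
    )
  })
  validate_rule_table(tab)
  if (cache) .rules_cache$table <- tab
  tab
}

.rules_cache <- new.env(parent = emptyenv())

# every rule id the engine dereferences at run time
REQUIRED_RULE_IDS <- c(
  "CLS-STAGE", "CLS-BMI", "CLS-NRI-EQ", "CLS-NRI-CLASS", "CLS-ASMM-EQ",
  "CLS-SARC", "CLS-CACHEXIA",
  "ENE-HB-MALE", "ENE-HB-FEMALE", "ENE-MIFFLIN", "ENE-FACTOR",
  "NUT-KCAL-PER-G", "NUT-PROT-CACHECTIC", "NUT-PROT-GPKG",
  "NUT-PROT-GPKG-SARC", "NUT-PROT-REFBMI-UNDER", "NUT-PROT-REFBMI-OBESE",
  "NUT-CARB", "NUT-CARB-PCO2", "NUT-SUGAR", "NUT-SUGAR-T2DM", "NUT-SATFAT",
  "NUT-CHOL", "NUT-CHOL-HC", "NUT-SODIUM", "NUT-CALCIUM", "NUT-FIBER",
  "NUT-MEALS", "NUT-SUPP-CACHECTIC", "NUT-SUPP-SARC-LEAN", "NUT-SUPP-SARC",
  "NUT-SUPP-DEFAULT"
)

validate_rule_table <- function(tab) {
  missing <- setdiff(REQUIRED_RULE_IDS, tab$id)
  if (length(missing) > 0) {
    abort(paste0("rule table is incomplete; missing rule id(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tab$id)) {
    abort("rule table contains duplicated rule ids")
  }
  bad <- !tab$provenance %in% c("guideline", "assumption")
  if (any(bad)) {
    abort(paste0("invalid provenance for rule(s): ",
                 paste(tab$id[bad], collapse = ", "),
                 " (must be 'guideline' or 'assumption')"))
  }
  invisible(tab)
}

# constant lookup: rule_value("NUT-SODIUM", "max_mg")
rule_value <- function(id, name, rules = nutrition_rules()) {
  i <- match(id, rules$id)
  if (is.na(i)) abort(paste0("unknown rule id: ", id))
  v <- rules$values[[i]][[name]]
  if (is.null(v)) abort(paste0("rule ", id, " has no constant '", name, "'"))
  v
}

rule_meta <- function(id, rules = nutrition_rules()) {
  i <- match(id, rules$id)
  if (is.na(i)) abort(paste0("unknown rule id: ", id))
  list(id = rules$id[i], description = rules$description[i],
       provenance = rules$provenance[i], fields = rules$fields[[i]])
}

# build one trace row per (patient, rule, field)
trace_rows <- function(id, patient_id, fields = NULL, rules = nutrition_rules()) {
  m <- rule_meta(id, rules)
  f <- fields %||% m$fields
  tibble::tibble(
    id = rep(patient_id, each = length(f)),
    rule_id = m$id,
    description = m$description,
    field = rep(f, times = length(patient_id)),
    provenance = m$provenance
  )
}
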