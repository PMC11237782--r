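#' Full nutritional assessment of a cohort
#'
#' One-call pipeline: validate, classify, recommend. Returns a
#' `copd_assessment` tibble that carries the complete per-patient rule trace
#' and supports [tidy()], [glance()], [ggplot2::autoplot()] and the report
#' writers.
#'
#' @param data data frame of raw patient records (see [validate_patients()]
#'   for the schema).
#' @return A tibble of class `copd_assessment`: input columns plus every
#'   classification and recommendation column.
#' @examples
#' a <- generate_cohort(10, seed = 42) |> assess_patients()
#' glance(a)
#' @export
assess_patients <- function(data) {
  out <- data |> validate_patients() |> classify_patients() |>
    recommend_nutrition()
  class(out) <- c("copd_assessment", class(out))
  out
}

#' Per-patient rule trace
#'
#' The explainability contract: every classification and recommendation field
#' of every patient is backed by at least one fired rule. Provenance
#' distinguishes `"guideline"` constants from `"assumption"` values the
#' package fixed where the rule base stated only a direction.
#'
#' @param x a `copd_assessment` (or any tibble produced by
#'   [classify_patients()] / [recommend_nutrition()]).
#' @return tibble with columns `id`, `rule_id`, `description`, `field`,
#'   `provenance`, one row per (patient, rule, field).
#' @examples
#' a <- generate_cohort(2, seed = 1) |> assess_patients()
#' rule_trace(a)
#' @export
rule_trace <- function(x) {
  tr <- attr(x, "trace")
  if (is.null(tr)) abort("no rule trace attached; run assess_patients()")
  tr
}

#' @describeIn assess_patients long tibble of the five classification labels
#'   per patient (`id`, `label_type`, `label`).
#' @param x a `copd_assessment`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.copd_assessment <- function(x, ...) {
  tibble::as_tibble(x)[, c("id", "phenotype", "copd_stage", "nri_class",
                           "sarcopenia_level", "cachectic")] |>
    dplyr::mutate(dplyr::across(-"id", as.character)) |>
    tidyr::pivot_longer(-"id", names_to = "label_type", values_to = "label")
}

#' @describeIn assess_patients one-row cohort summary: counts by status and
#'   mean energy prescription.
#' @exportS3Method generics::glance
glance.copd_assessment <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    n_sarcopenic = sum(x$sarcopenia_level != "none"),
    n_cachectic = sum(x$cachectic),
    n_nutritional_risk = sum(x$nri_class != "absence"),
    mean_bmr_kcal = mean(x$bmr_kcal),
    mean_energy_kcal = mean(x$energy_kcal),
    mean_protein_g = mean(x$protein_g)
  )
}

#' Plot the classification mix of an assessed cohort
#'
#' Stacked bar chart of anthropometric phenotype by COPD stage, filled by
#' nutritional risk class.
#'
#' @param object a `copd_assessment`.
#' @param ... unused.
#' @return a ggplot object.
#' @examples
#' a <- generate_cohort(50, seed = 7) |> assess_patients()
#' ggplot2::autoplot(a)
#' @exportS3Method ggplot2::autoplot
autoplot.copd_assessment <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$phenotype, fill = .data$nri_class)) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(ggplot2::vars(.data$copd_stage), nrow = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1,
                               name = "NRI class", drop = FALSE) +
    ggplot2::labs(x = "anthropometric phenotype", y = "patients") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
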