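# Core health-impact chain: dose -> excess cancer risk -> expected cases ->
# expected deaths. All tables are long-format tibbles keyed by age group,
# region and (where applicable) period; values stay real-valued (fractional
# persons) until report formatting.

#' Risk coefficients for the carcinogenic dose-response step
#'
#' Bundles the cancer slope factor (CSF) and the cancer mortality risk used
#' by the chain. The CSF is the excess lifetime cancer risk per unit of
#' lifetime average daily dose (per pg-TEQ/kg/day); the mortality risk is
#' the probability that a cancer case is fatal, conventionally derived from
#' an all-cancer survival rate via [mortality_risk_from_survival()].
#'
#' @param csf Cancer slope factor, a nonnegative number, per (pg-TEQ/kg/day).
#' @param mortality_risk Probability in `[0, 1]` that a cancer case is fatal.
#' @return An object of class `bpthia_coeffs`.
#' @examples
#' risk_coefficients(csf = 1e-4, mortality_risk = 0.2278)
#' @export
risk_coefficients <- function(csf, mortality_risk) {
  assert_scalar_number(csf, "csf", min = 0)
  assert_scalar_number(mortality_risk, "mortality_risk", min = 0, max = 1)
  structure(list(csf = csf, mortality_risk = mortality_risk),
            class = "bpthia_coeffs")
}

#' Cancer mortality risk from an all-cancer survival rate
#'
#' The complement of the survival rate: a published 1-year all-cancer
#' survival of 77.22% corresponds to a mortality risk of 22.78%.
#'
#' @param survival_rate Survival probability in `[0, 1]`.
#' @return `1 - survival_rate`.
#' @examples
#' mortality_risk_from_survival(0.7722)
#' @export
mortality_risk_from_survival <- function(survival_rate) {
  assert_scalar_number(survival_rate, "survival_rate", min = 0, max = 1)
  1 - survival_rate
}

#' Excess lifetime cancer risk from exposure dose
#'
#' Multiplies each cell's lifetime average daily dose (LADD) by the cancer
#' slope factor: `risk[i, j] = ladd[i, j] * csf`. The output carries the
#' same (age_group, region) grid as the input.
#'
#' @param exposure Tibble with columns `age_group`, `region`, `ladd`
#'   (pg-TEQ/kg/day, nonnegative), complete over its age-by-region grid.
#' @param coeffs A [risk_coefficients()] object.
#' @return Tibble with columns `age_group`, `region`, `risk`.
#' @examples
#' exposure <- tibble::tibble(age_group = "working_age", region = "northern",
#'                            ladd = 1.52e-3)
#' compute_cancer_risk(exposure, risk_coefficients(1e-4, 0.2278))
#' @export
compute_cancer_risk <- function(exposure, coeffs) {
  assert_cols(exposure, c("age_group", "region", "ladd"), "exposure")
  stopifnot(inherits(coeffs, "bpthia_coeffs"))
  check_complete_grid(exposure,
                      list(age_group = unique(exposure$age_group),
                           region = unique(exposure$region)),
                      "exposure")
  bad <- exposure[is.na(exposure$ladd) | exposure$ladd < 0, ]
  if (nrow(bad) > 0) {
    abort_validation(sprintf(
      "exposure has negative or missing ladd at (%s, %s).",
      bad$age_group[1], bad$region[1]))
  }
  dplyr::transmute(exposure, .data$age_group, .data$region,
                   risk = .data$ladd * coeffs$csf)
}

#' Expected number of people at risk of cancer
#'
#' `er[i, j] = risk[i, j] * pop[i, j, t]` for the requested period. Counts
#' are kept fractional; no rounding happens here.
#'
#' @param risk Tibble with columns `age_group`, `region`, `risk`.
#' @param population Tibble with columns `age_group`, `region`, `period`,
#'   `count` (persons, nonnegative).
#' @param period Period id (single string) present in `population`.
#' @return Tibble with columns `age_group`, `region`, `period`,
#'   `expected_cases`.
#' @export
expected_at_risk <- function(risk, population, period) {
  assert_cols(risk, c("age_group", "region", "risk"), "risk")
  assert_cols(population, c("age_group", "region", "period", "count"),
              "population")
  stopifnot(is.character(period), length(period) == 1)
  pop_t <- population[population$period == period, ]
  if (nrow(pop_t) == 0) {
    abort_validation(sprintf("period '%s' is absent from the population table.",
                             period))
  }
  joined <- dplyr::inner_join(risk, pop_t, by = c("age_group", "region"))
  if (nrow(joined) < nrow(risk)) {
    gone <- dplyr::anti_join(risk, pop_t, by = c("age_group", "region"))
    abort_validation(sprintf(
      "population lacks cell (%s, %s) for period '%s'.",
      gone$age_group[1], gone$region[1], period))
  }
  dplyr::transmute(joined, .data$age_group, .data$region, .data$period,
                   expected_cases = .data$risk * .data$count)
}

#' Expected cancer deaths
#'
#' `d[i, j] = er[i, j] * mortality_risk`.
#'
#' @param er Output of [expected_at_risk()] (columns `age_group`, `region`,
#'   `expected_cases`, optionally `period`).
#' @param coeffs A [risk_coefficients()] object.
#' @return The input with `expected_cases` replaced by `deaths`.
#' @export
expected_deaths <- function(er, coeffs) {
  assert_cols(er, c("age_group", "region", "expected_cases"), "er")
  stopifnot(inherits(coeffs, "bpthia_coeffs"))
  out <- dplyr::mutate(er, deaths = .data$expected_cases * coeffs$mortality_risk)
  dplyr::select(out, -"expected_cases")
}
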