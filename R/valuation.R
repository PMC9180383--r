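# Valuation: value-of-a-statistical-life (VSL) transfer across years,
# CPI deflation, discounted period-average schedules, and monetization of
# expected deaths. All internal money is USD.

#' Value-transfer parameters
#'
#' Parameters for moving a VSL estimate from its study year to the analysis
#' year: a wage-growth adjustment with an earnings elasticity, and a CPI
#' deflation. Monetary inputs are USD; `exchange_rate` (TWD per USD) is only
#' used when ingesting TWD-denominated sources.
#'
#' @param vsl_base VSL in the study year, USD (> 0).
#' @param earnings_elasticity Elasticity of the VSL with respect to earnings.
#' @param wage_base,wage_target Average monthly earnings (USD) in the study
#'   year and the analysis year (> 0).
#' @param cpi_base,cpi_target Consumer price indices for the study year and
#'   the analysis year, any common base (> 0).
#' @param exchange_rate TWD per USD (> 0), optional.
#' @return An object of class `bpthia_vt_params`.
#' @export
value_transfer_params <- function(vsl_base, earnings_elasticity,
                                  wage_base, wage_target,
                                  cpi_base, cpi_target,
                                  exchange_rate = NA_real_) {
  assert_scalar_number(vsl_base, "vsl_base")
  if (vsl_base <= 0) abort_validation("vsl_base must be positive.")
  assert_scalar_number(earnings_elasticity, "earnings_elasticity")
  for (nm in c("wage_base", "wage_target", "cpi_base", "cpi_target")) {
    v <- get(nm)
    assert_scalar_number(v, nm)
    if (v <= 0) abort_validation(sprintf("%s must be positive.", nm))
  }
  if (!is.na(exchange_rate) && exchange_rate <= 0) {
    abort_validation("exchange_rate must be positive.")
  }
  structure(list(vsl_base = vsl_base,
                 earnings_elasticity = earnings_elasticity,
                 wage_base = wage_base, wage_target = wage_target,
                 cpi_base = cpi_base, cpi_target = cpi_target,
                 exchange_rate = exchange_rate),
            class = "bpthia_vt_params")
}

#' Wage-adjusted nominal VSL for the analysis year
#'
#' Applies the earnings elasticity to the percent wage change between the
#' study year and the analysis year:
#' `vsl_base * (1 + elasticity * (wage_target - wage_base) / wage_base)`.
#'
#' @param params A [value_transfer_params()] object.
#' @return The nominal VSL in analysis-year USD.
#' @export
transfer_vsl_nominal <- function(params) {
  stopifnot(inherits(params, "bpthia_vt_params"))
  growth <- (params$wage_target - params$wage_base) / params$wage_base
  params$vsl_base * (1 + params$earnings_elasticity * growth)
}

#' CPI deflation to real terms
#'
#' `nominal * cpi_base / cpi_target`.
#'
#' @param params A [value_transfer_params()] object.
#' @param nominal A nominal USD amount (> 0).
#' @return The real (base-year-price) USD amount.
#' @export
deflate_vsl_real <- function(params, nominal) {
  stopifnot(inherits(params, "bpthia_vt_params"))
  assert_scalar_number(nominal, "nominal")
  nominal * params$cpi_base / params$cpi_target
}

#' Discounting specification for VSL schedules
#'
#' @param annual_rate Annual real discount rate, `0 <= rate < 1`.
#' @param base_year Calendar year with discount factor 1.
#' @param convention `"geometric_annual"` discounts each calendar year of a
#'   period geometrically and averages within the period;
#'   `"fixture"` passes a user-supplied schedule through verbatim (used when
#'   a published schedule is canonical).
#' @return An object of class `bpthia_discount`.
#' @export
discount_spec <- function(annual_rate = 0.02, base_year = 2020,
                          convention = c("geometric_annual", "fixture")) {
  assert_scalar_number(annual_rate, "annual_rate", min = 0)
  if (annual_rate >= 1) abort_validation("annual_rate must be < 1.")
  assert_scalar_number(base_year, "base_year")
  convention <- match.arg(convention)
  structure(list(annual_rate = annual_rate, base_year = base_year,
                 convention = convention),
            class = "bpthia_discount")
}

#' Build a VSL schedule over periods
#'
#' Under the `geometric_annual` convention each period's VSL is the base
#' VSL for the age group times the mean of `(1 + rate)^-(y - base_year)`
#' over the calendar years `y` spanned by the period. Under the `fixture`
#' convention the supplied `schedule` is validated and returned verbatim.
#'
#' @param base_vsl_by_group Named numeric vector, age group id -> USD (> 0).
#' @param periods Tibble with columns `id`, `start_year`, `end_year`.
#' @param spec A [discount_spec()] object.
#' @param schedule Required for the `fixture` convention: tibble with
#'   columns `age_group`, `period`, `vsl`.
#' @return Tibble with columns `age_group`, `period`, `vsl`.
#' @examples
#' periods <- tibble::tibble(id = "2021-2025", start_year = 2021, end_year = 2025)
#' build_vsl_schedule(c(children = 100), periods, discount_spec(0.02, 2020))
#' @export
build_vsl_schedule <- function(base_vsl_by_group, periods, spec,
                               schedule = NULL) {
  stopifnot(inherits(spec, "bpthia_discount"))
  assert_cols(periods, c("id", "start_year", "end_year"), "periods")
  if (spec$convention == "fixture") {
    if (is.null(schedule)) {
      abort_validation(
        "the 'fixture' convention needs a `schedule` (age_group, period, vsl).")
    }
    assert_cols(schedule, c("age_group", "period", "vsl"), "schedule")
    return(tibble::as_tibble(schedule))
  }
  if (is.null(names(base_vsl_by_group)) || any(base_vsl_by_group <= 0)) {
    abort_validation("base_vsl_by_group must be a named vector of positive USD.")
  }
  factors <- vapply(seq_len(nrow(periods)), function(k) {
    years <- seq(periods$start_year[k], periods$end_year[k])
    mean((1 + spec$annual_rate)^-(years - spec$base_year))
  }, numeric(1))
  tidyr::expand_grid(age_group = names(base_vsl_by_group),
                     period = periods$id) |>
    dplyr::left_join(tibble::tibble(period = periods$id, .f = factors),
                     by = "period") |>
    dplyr::mutate(vsl = unname(base_vsl_by_group[.data$age_group]) * .data$.f) |>
    dplyr::select("age_group", "period", "vsl")
}

#' Monetize expected cancer deaths
#'
#' `mdc[i, j, t] = d[i, j, t] * vsl[i, t]`, the expected monetary value of
#' cancer mortality for each cell.
#'
#' Published tables of this quantity are sometimes printed from expected
#' deaths rounded to a fixed number of decimals; `deaths_digits` reproduces
#' that convention (the packaged Taiwan scenario uses 4). Leave `NULL` for
#' full-precision monetization.
#'
#' @param deaths Tibble with columns `age_group`, `region`, `deaths`, and
#'   `period` (or supply `period` as an argument for a single-period slice).
#' @param schedule VSL schedule tibble (`age_group`, `period`, `vsl`).
#' @param period Optional period id attached to `deaths` when absent.
#' @param deaths_digits Optional integer: round deaths to this many decimal
#'   places before monetizing.
#' @return Tibble with columns `age_group`, `region`, `period`, `mdc` (USD).
#' @export
monetize_deaths <- function(deaths, schedule, period = NULL,
                            deaths_digits = NULL) {
  assert_cols(deaths, c("age_group", "region", "deaths"), "deaths")
  assert_cols(schedule, c("age_group", "period", "vsl"), "schedule")
  if (!"period" %in% names(deaths)) {
    if (is.null(period)) {
      abort_validation("deaths carries no period column and no `period` given.")
    }
    deaths <- dplyr::mutate(deaths, period = period)
  }
  if (any(schedule$vsl <= 0, na.rm = TRUE)) {
    abort_validation("VSL schedule values must be positive.")
  }
  joined <- dplyr::left_join(deaths, schedule, by = c("age_group", "period"))
  if (anyNA(joined$vsl)) {
    gone <- joined[is.na(joined$vsl), ]
    abort_validation(sprintf(
      "VSL schedule lacks cell (%s, %s).", gone$age_group[1], gone$period[1]))
  }
  d <- joined$deaths
  if (!is.null(deaths_digits)) d <- round(d, deaths_digits)
  dplyr::transmute(joined, .data$age_group, .data$region, .data$period,
                   mdc = d * .data$vsl)
}
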