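# Synthetic scenarios with the statistical structure the analysis assumes:
# K sub-regions plus a first-class national aggregate, three age groups,
# T periods, log-uniform doses, drifting populations, geometric-discounted
# VSL schedules and a linear reduction plan.

#' Configuration for the synthetic-scenario generator
#'
#' Defaults emulate the Taiwan study conditions: four sub-regions, eleven
#' periods (a base year plus ten 5-year intervals), doses spanning the
#' published regional LADD range, populations spanning the regional
#' age-cell counts with a per-period decline of about 2.8% (roughly a 25%
#' fall over ten periods), VSLs spanning the published age-group values,
#' a 2%/year geometric discount and a plan that halves emissions by the
#' final period.
#'
#' @param n_regions Number of sub-regions (>= 1).
#' @param n_periods Number of periods (>= 1); the first is the base period.
#' @param seed Integer seed; identical seeds give identical scenarios.
#' @param ladd_range Positive interval for log-uniform LADD draws
#'   (pg-TEQ/kg/day).
#' @param pop_range Positive interval for per-cell population draws
#'   (persons).
#' @param vsl_range Positive interval for age-group base VSL draws (USD).
#' @param base_emission_range Positive interval for regional base emissions
#'   (grams TEQ).
#' @param reduction_fraction Fraction of base emissions remaining in the
#'   final period, in (0, 1].
#' @param drift Per-period relative population decline in `[0, 1)`.
#' @return An object of class `bpthia_synth_config`.
#' @export
synth_config <- function(n_regions = 4, n_periods = 11, seed = 1,
                         ladd_range = c(8.37e-5, 2.79e-2),
                         pop_range = c(5e4, 7.5e6),
                         vsl_range = c(2e6, 2.6e7),
                         base_emission_range = c(0.68, 32),
                         reduction_fraction = 0.5,
                         drift = 0.0283) {
  assert_scalar_number(n_regions, "n_regions", min = 1)
  assert_scalar_number(n_periods, "n_periods", min = 1)
  assert_scalar_number(seed, "seed")
  for (nm in c("ladd_range", "pop_range", "vsl_range",
               "base_emission_range")) {
    r <- get(nm)
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
      abort_validation(sprintf("%s must be an ordered positive interval.", nm))
    }
  }
  assert_scalar_number(reduction_fraction, "reduction_fraction")
  if (reduction_fraction <= 0 || reduction_fraction > 1) {
    abort_validation("reduction_fraction must lie in (0, 1].")
  }
  assert_scalar_number(drift, "drift", min = 0)
  if (drift >= 1) abort_validation("drift must be < 1.")
  structure(list(n_regions = n_regions, n_periods = n_periods, seed = seed,
                 ladd_range = ladd_range, pop_range = pop_range,
                 vsl_range = vsl_range,
                 base_emission_range = base_emission_range,
                 reduction_fraction = reduction_fraction, drift = drift),
            class = "bpthia_synth_config")
}

runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

#' Generate a random scenario
#'
#' Draws a complete, validating scenario from a [synth_config()]:
#' log-uniform LADDs per (age group, region) including the national
#' aggregate; national populations drawn uniform per age group, declined by
#' `drift` per period and allocated to sub-regions with random shares via
#' [allocate_population()]; age-group base VSLs drawn uniform (sorted
#' ascending with age, mirroring the study pattern) and discounted
#' geometrically; and regional base emissions reduced linearly to
#' `reduction_fraction` of base by the final period against a constant
#' baseline.
#'
#' @param config A [synth_config()] object.
#' @return A [scenario()] object.
#' @examples
#' s <- generate_scenario(synth_config(n_regions = 2, n_periods = 3, seed = 7))
#' nrow(validate_scenario(s)) == 0
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "bpthia_synth_config"))
  with_seed(config$seed, {
    k <- config$n_regions
    t_n <- config$n_periods
    groups <- c("children", "working_age", "older")
    sub_ids <- sprintf("region_%02d", seq_len(k))
    nat_id <- "national"

    shares <- stats::runif(k)
    shares <- stats::setNames(shares / sum(shares), sub_ids)

    age_groups <- tibble::tibble(
      id = groups, min_age = c(0, 15, 65), max_age = c(14, 64, NA),
      label = c("Children (0-14)", "Working-age adults (15-64)",
                "Older adults (65+)"))
    regions <- tibble::tibble(
      id = c(sub_ids, nat_id),
      label = c(sub_ids, "National aggregate"),
      national = c(rep(FALSE, k), TRUE),
      share = c(unname(shares), NA_real_))
    start <- c(2020, seq(2021, by = 5, length.out = max(t_n - 1, 0)))
    periods <- tibble::tibble(
      id = sprintf("p%02d", seq_len(t_n)),
      start_year = start[seq_len(t_n)],
      end_year = c(2020, seq(2025, by = 5,
                             length.out = max(t_n - 1, 0)))[seq_len(t_n)])

    exposure <- tidyr::expand_grid(age_group = groups,
                                   region = c(sub_ids, nat_id)) |>
      dplyr::mutate(ladd = runif_log(dplyr::n(), config$ladd_range))

    nat_base <- stats::runif(3, config$pop_range[1], config$pop_range[2]) * k
    national <- tidyr::expand_grid(age_group = groups, period = periods$id) |>
      dplyr::left_join(tibble::tibble(period = periods$id,
                                      decline = (1 - config$drift)^
                                        (seq_len(t_n) - 1)),
                       by = "period") |>
      dplyr::mutate(count = unname(stats::setNames(nat_base, groups)[.data$age_group]) *
                      .data$decline) |>
      dplyr::select("age_group", "period", "count")
    population <- allocate_population(national, shares, national_id = nat_id)

    base_vsl <- sort(stats::runif(3, config$vsl_range[1], config$vsl_range[2]))
    vsl <- build_vsl_schedule(stats::setNames(base_vsl, groups), periods,
                              discount_spec(0.02, periods$start_year[1],
                                            "geometric_annual"))

    base_e <- stats::setNames(runif_log(k, config$base_emission_range), sub_ids)
    base_e <- c(base_e, stats::setNames(sum(base_e), nat_id))
    segments <- if (t_n > 1) {
      list(trajectory_segment(1, t_n, 1, config$reduction_fraction))
    } else {
      NULL
    }
    trajectory <- if (t_n > 1) {
      build_trajectory(base_e, segments, periods)
    } else {
      dplyr::bind_rows(
        tibble::tibble(region = names(base_e), period = periods$id,
                       path = "policy", grams = unname(base_e)),
        tibble::tibble(region = names(base_e), period = periods$id,
                       path = "baseline", grams = unname(base_e)))
    }

    scenario(
      age_groups = age_groups, regions = regions, periods = periods,
      exposure = exposure,
      coeffs = risk_coefficients(csf = 1e-4, mortality_risk = 0.2278),
      population = population, vsl = vsl, trajectory = trajectory,
      discount = discount_spec(0.02, periods$start_year[1],
                               "geometric_annual"),
      provenance = sprintf("synthetic scenario, seed %d", config$seed)
    )
  })
}

#' Allocate national population to regions by fixed shares
#'
#' `pop[i, j, t] = national[i, t] * share[j]` for every sub-region; the
#' national aggregate (when `national_id` is given) keeps the national
#' count. Shares are applied uniformly across age groups.
#'
#' @param national Tibble with columns `age_group`, `period`, `count`.
#' @param shares Named numeric vector, region id -> share in `[0, 1]`;
#'   the shares may sum to at most 1.
#' @param national_id Optional id under which the national counts are kept.
#' @return Tibble `age_group`, `region`, `period`, `count`.
#' @examples
#' nat <- tibble::tibble(age_group = "children", period = "2021-2025",
#'                       count = 2843731)
#' allocate_population(nat, c(northern = 0.4448))
#' @export
allocate_population <- function(national, shares, national_id = NULL) {
  assert_cols(national, c("age_group", "period", "count"), "national")
  if (is.null(names(shares)) || any(!nzchar(names(shares)))) {
    abort_validation("shares must be a named vector of region shares.")
  }
  if (any(shares < 0)) abort_validation("negative population share.")
  if (sum(shares) > 1 + 1e-9) {
    abort_validation("shares must sum to at most 1 (the national aggregate holds the full count).")
  }
  out <- dplyr::bind_rows(lapply(names(shares), function(r) {
    dplyr::transmute(national, .data$age_group, region = r, .data$period,
                     count = .data$count * shares[[r]])
  }))
  if (!is.null(national_id)) {
    out <- dplyr::bind_rows(
      out,
      dplyr::transmute(national, .data$age_group, region = national_id,
                       .data$period, .data$count))
  }
  out
}
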