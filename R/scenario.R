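# The Scenario container: everything one pipeline run consumes, plus
# structured validation and CSV/YAML bundle round-tripping.

#' Assemble a scenario
#'
#' Bundles the index sets (age groups, regions, periods), the exposure
#' table, risk coefficients, populations, VSL schedule and parameters, and
#' the emission trajectory into one object consumed by [run_pipeline()].
#'
#' @param age_groups Tibble `id`, `min_age`, `max_age` (NA = open), `label`.
#' @param regions Tibble `id`, `label`, `national` (logical, exactly one
#'   TRUE), optional `share` (population share of sub-regions).
#' @param periods Tibble `id`, `start_year`, `end_year`, chronologically
#'   ordered and non-overlapping.
#' @param exposure Tibble `age_group`, `region`, `ladd` (pg-TEQ/kg/day).
#' @param coeffs A [risk_coefficients()] object.
#' @param population Tibble `age_group`, `region`, `period`, `count`.
#' @param vsl VSL schedule tibble `age_group`, `period`, `vsl` (USD).
#' @param trajectory Tibble `region`, `period`, `path`, `grams`.
#' @param vt_params Optional [value_transfer_params()] object.
#' @param discount Optional [discount_spec()] object.
#' @param deaths_digits Optional integer passed to [monetize_deaths()];
#'   scenarios reproducing published tables printed from rounded expected
#'   deaths set this (the packaged Taiwan scenario uses 4).
#' @param reference Optional named list of published reference tables kept
#'   alongside the scenario for cross-checking (not used by the pipeline).
#' @param provenance Free-text description of where the inputs come from.
#' @return An object of class `bpt_scenario`.
#' @export
scenario <- function(age_groups, regions, periods, exposure, coeffs,
                     population, vsl, trajectory,
                     vt_params = NULL, discount = NULL,
                     deaths_digits = NULL, reference = NULL,
                     provenance = "") {
  s <- structure(list(
    age_groups = tibble::as_tibble(age_groups),
    regions = tibble::as_tibble(regions),
    periods = tibble::as_tibble(periods),
    exposure = tibble::as_tibble(exposure),
    coeffs = coeffs,
    population = tibble::as_tibble(population),
    vsl = tibble::as_tibble(vsl),
    trajectory = tibble::as_tibble(trajectory),
    vt_params = vt_params,
    discount = discount,
    deaths_digits = deaths_digits,
    reference = reference,
    provenance = provenance
  ), class = "bpt_scenario")
  s
}

#' @export
print.bpt_scenario <- function(x, ...) {
  nat <- x$regions$id[x$regions$national]
  cat("<bpt_scenario>\n")
  cat(sprintf("  %d age groups x %d regions (national: %s) x %d periods\n",
              nrow(x$age_groups), nrow(x$regions),
              if (length(nat)) nat else "<none>", nrow(x$periods)))
  if (nzchar(x$provenance)) {
    cat(" ", substr(gsub("\\s+", " ", x$provenance), 1, 70), "...\n")
  }
  invisible(x)
}

finding <- function(severity, key, message) {
  tibble::tibble(severity = severity, key = key, message = message)
}

#' Validate a scenario
#'
#' Checks every structural invariant the pipeline relies on and returns a
#' table of findings rather than throwing: an empty table means the
#' scenario is valid. Error-severity findings block [run_pipeline()];
#' warning-severity findings do not.
#'
#' @param s A [scenario()] object.
#' @return Tibble with columns `severity` (`"error"`/`"warning"`), `key`
#'   (path to the offending cell), `message`.
#' @export
validate_scenario <- function(s) {
  stopifnot(inherits(s, "bpt_scenario"))
  f <- list()
  add <- function(...) f[[length(f) + 1]] <<- finding(...)

  ag <- s$age_groups
  if (anyDuplicated(ag$id)) add("error", "age_groups", "age group ids are not unique")
  rg <- s$regions
  if (anyDuplicated(rg$id)) add("error", "regions", "region ids are not unique")
  n_nat <- sum(rg$national)
  if (n_nat != 1) {
    add("error", "regions",
        sprintf("exactly one national region is required, found %d", n_nat))
  }
  if ("share" %in% names(rg)) {
    sh <- rg$share[!rg$national]
    if (any(sh < 0, na.rm = TRUE)) {
      add("error", "regions$share", "negative population share")
    }
    tot <- sum(sh, na.rm = TRUE)
    if (length(sh) && all(!is.na(sh))) {
      # Shares may legitimately sum to slightly under 1 (areas excluded
      # from the regional breakdown); more than 1% unallocated, or any
      # excess over 1, is suspicious.
      if (tot > 1 + 1e-6) {
        add("error", "regions$share",
            sprintf("sub-region shares sum to %.6f, above 1", tot))
      } else if (tot < 0.99) {
        add("warning", "regions$share",
            sprintf("sub-region shares sum to %.6f, leaving over 1%% of the population unallocated", tot))
      }
    }
  }

  pd <- s$periods
  if (any(pd$start_year > pd$end_year)) {
    add("error", "periods", "a period has start_year > end_year")
  }
  if (nrow(pd) > 1) {
    if (any(diff(pd$start_year) <= 0)) {
      add("error", "periods", "periods are not chronologically ordered")
    }
    if (any(pd$start_year[-1] <= pd$end_year[-nrow(pd)])) {
      add("error", "periods", "periods overlap")
    }
  }

  grid2 <- tidyr::expand_grid(age_group = ag$id, region = rg$id)
  m <- dplyr::anti_join(grid2, s$exposure, by = c("age_group", "region"))
  if (nrow(m) > 0) {
    add("error", sprintf("exposure[%s,%s]", m$age_group[1], m$region[1]),
        "missing exposure cell")
  }
  if (any(s$exposure$ladd < 0, na.rm = TRUE)) {
    b <- s$exposure[s$exposure$ladd < 0, ]
    add("error", sprintf("exposure[%s,%s]", b$age_group[1], b$region[1]),
        "negative LADD")
  }

  if (!inherits(s$coeffs, "bpthia_coeffs")) {
    add("error", "coeffs", "coeffs must be a risk_coefficients() object")
  }

  grid3 <- tidyr::expand_grid(age_group = ag$id, region = rg$id,
                              period = pd$id)
  m <- dplyr::anti_join(grid3, s$population,
                        by = c("age_group", "region", "period"))
  if (nrow(m) > 0) {
    add("error", sprintf("population[%s,%s,%s]",
                         m$age_group[1], m$region[1], m$period[1]),
        "missing population cell")
  }
  if (any(s$population$count < 0, na.rm = TRUE)) {
    b <- s$population[s$population$count < 0, ]
    add("error", sprintf("population[%s,%s,%s]",
                         b$age_group[1], b$region[1], b$period[1]),
        "negative population count")
  }

  gridv <- tidyr::expand_grid(age_group = ag$id, period = pd$id)
  m <- dplyr::anti_join(gridv, s$vsl, by = c("age_group", "period"))
  if (nrow(m) > 0) {
    add("error", sprintf("vsl[%s,%s]", m$age_group[1], m$period[1]),
        "missing VSL cell")
  }
  if (any(s$vsl$vsl <= 0, na.rm = TRUE)) {
    b <- s$vsl[s$vsl$vsl <= 0, ]
    add("error", sprintf("vsl[%s,%s]", b$age_group[1], b$period[1]),
        "nonpositive VSL")
  }

  tr <- s$trajectory
  for (p in c("policy", "baseline")) {
    gridt <- tidyr::expand_grid(region = rg$id, period = pd$id, path = p)
    m <- dplyr::anti_join(gridt, tr, by = c("region", "period", "path"))
    if (nrow(m) > 0) {
      add("error", sprintf("trajectory[%s,%s,%s]", m$region[1], m$period[1], p),
          "missing emission cell")
    }
  }
  if (any(tr$grams <= 0, na.rm = TRUE)) {
    b <- tr[tr$grams <= 0, ]
    add("error", sprintf("trajectory[%s,%s,%s]",
                         b$region[1], b$period[1], b$path[1]),
        "nonpositive emissions")
  }
  wide <- tidyr::pivot_wider(tr, names_from = "path", values_from = "grams")
  if (all(c("policy", "baseline") %in% names(wide))) {
    b <- wide[!is.na(wide$policy) & !is.na(wide$baseline) &
                wide$policy > wide$baseline + 1e-12, ]
    if (nrow(b) > 0) {
      add("error", sprintf("trajectory[%s,%s]", b$region[1], b$period[1]),
          "policy emissions exceed baseline emissions")
    }
  }

  if (length(f) == 0) {
    return(tibble::tibble(severity = character(), key = character(),
                          message = character()))
  }
  dplyr::bind_rows(f)
}

#' Write a scenario bundle to a directory
#'
#' The bundle is a directory of long-format CSVs plus a `scenario.yaml`
#' manifest carrying the scalar parameters. [read_scenario()] restores it
#' losslessly.
#'
#' @param s A [scenario()] object.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(s, dir) {
  stopifnot(inherits(s, "bpt_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(s$age_groups, file.path(dir, "age_groups.csv"))
  readr::write_csv(s$regions, file.path(dir, "regions.csv"))
  readr::write_csv(s$periods, file.path(dir, "periods.csv"))
  readr::write_csv(s$exposure, file.path(dir, "exposure.csv"))
  readr::write_csv(s$population, file.path(dir, "population.csv"))
  readr::write_csv(s$vsl, file.path(dir, "vsl_schedule.csv"))
  readr::write_csv(s$trajectory, file.path(dir, "emission_trajectory.csv"))
  manifest <- list(
    coefficients = list(csf = s$coeffs$csf,
                        mortality_risk = s$coeffs$mortality_risk),
    deaths_digits = s$deaths_digits,
    provenance = s$provenance
  )
  if (!is.null(s$vt_params)) {
    manifest$value_transfer <- unclass(s$vt_params)
  }
  if (!is.null(s$discount)) manifest$discount <- unclass(s$discount)
  yaml::write_yaml(manifest, file.path(dir, "scenario.yaml"))
  invisible(dir)
}

#' Read a scenario bundle written by [write_scenario()]
#'
#' @param dir Bundle directory.
#' @return A [scenario()] object.
#' @export
read_scenario <- function(dir) {
  rd <- function(nm) read_table_csv(file.path(dir, nm))
  manifest <- yaml::read_yaml(file.path(dir, "scenario.yaml"))
  vt <- NULL
  if (!is.null(manifest$value_transfer)) {
    vt <- do.call(value_transfer_params, manifest$value_transfer[
      c("vsl_base", "earnings_elasticity", "wage_base", "wage_target",
        "cpi_base", "cpi_target", "exchange_rate")])
  }
  disc <- NULL
  if (!is.null(manifest$discount)) {
    disc <- discount_spec(manifest$discount$annual_rate,
                          manifest$discount$base_year,
                          manifest$discount$convention)
  }
  scenario(
    age_groups = rd("age_groups.csv"),
    regions = rd("regions.csv"),
    periods = rd("periods.csv"),
    exposure = rd("exposure.csv"),
    coeffs = risk_coefficients(manifest$coefficients$csf,
                               manifest$coefficients$mortality_risk),
    population = rd("population.csv"),
    vsl = rd("vsl_schedule.csv"),
    trajectory = rd("emission_trajectory.csv"),
    vt_params = vt,
    discount = disc,
    deaths_digits = manifest$deaths_digits,
    provenance = manifest$provenance %||% ""
  )
}
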