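# One-at-a-time uncertainty sweeps: perturb one key parameter, re-run the
# whole pipeline, and report the percent change in the per-gram benefit.

sweep_parameters <- c("vsl", "population", "csf", "mortality_risk", "ladd")

#' Specification of a one-at-a-time parameter sweep
#'
#' @param parameter One of `"vsl"`, `"population"`, `"csf"`,
#'   `"mortality_risk"`, `"ladd"`.
#' @param multipliers Positive multipliers applied to the parameter, one
#'   pipeline re-run each.
#' @param age_group,period Optional scope restriction (only cells matching
#'   both are perturbed); `NULL` means all.
#' @param replacement Optional absolute replacement table (currently for
#'   `parameter = "population"`): a full population tibble used instead of
#'   a multiplier (supply `multipliers = 1` alongside).
#' @return An object of class `bpthia_sweep_spec`.
#' @export
sweep_spec <- function(parameter, multipliers = c(0.9, 1.1),
                       age_group = NULL, period = NULL, replacement = NULL) {
  if (!is.character(parameter) || length(parameter) != 1 ||
      !parameter %in% sweep_parameters) {
    abort_validation(sprintf(
      "unknown sweep parameter '%s'; valid names: %s.",
      paste(parameter, collapse = ","),
      paste(sweep_parameters, collapse = ", ")))
  }
  if (!is.numeric(multipliers) || length(multipliers) == 0 ||
      any(multipliers <= 0)) {
    abort_validation("multipliers must be positive numbers.")
  }
  if (!is.null(replacement)) {
    assert_cols(replacement, c("age_group", "region", "period", "count"),
                "replacement")
  }
  structure(list(parameter = parameter, multipliers = multipliers,
                 age_group = age_group, period = period,
                 replacement = replacement),
            class = "bpthia_sweep_spec")
}

scoped <- function(df, spec, key_period = "period") {
  sel <- rep(TRUE, nrow(df))
  if (!is.null(spec$age_group) && "age_group" %in% names(df)) {
    sel <- sel & df$age_group %in% spec$age_group
  }
  if (!is.null(spec$period) && key_period %in% names(df)) {
    sel <- sel & df[[key_period]] %in% spec$period
  }
  sel
}

perturb_scenario <- function(s, spec, multiplier) {
  out <- s
  switch(spec$parameter,
    vsl = {
      sel <- scoped(s$vsl, spec)
      out$vsl$vsl[sel] <- s$vsl$vsl[sel] * multiplier
    },
    population = {
      if (!is.null(spec$replacement)) {
        out$population <- tibble::as_tibble(spec$replacement)
      } else {
        sel <- scoped(s$population, spec)
        out$population$count[sel] <- s$population$count[sel] * multiplier
      }
    },
    ladd = {
      sel <- scoped(s$exposure, spec)
      out$exposure$ladd[sel] <- s$exposure$ladd[sel] * multiplier
    },
    csf = {
      out$coeffs <- risk_coefficients(s$coeffs$csf * multiplier,
                                      s$coeffs$mortality_risk)
    },
    mortality_risk = {
      out$coeffs <- risk_coefficients(s$coeffs$csf,
                                      s$coeffs$mortality_risk * multiplier)
    }
  )
  out
}

extract_bpt <- function(report, level, age_group, region, period, path) {
  b <- report$tables$bpt
  rows <- b[b$level == level & b$period == period & b$path == path, ]
  if (level == "group") rows <- rows[rows$age_group == age_group, ]
  if (!is.null(region) && level != "national") rows <- rows[rows$region == region, ]
  if (nrow(rows) != 1) {
    abort_validation(sprintf(
      "BPT extraction at (%s, %s, %s) matched %d rows.", level, period, path,
      nrow(rows)))
  }
  rows$usd_per_gram
}

#' Run a one-at-a-time sweep
#'
#' Re-runs the full pipeline once per multiplier with the single
#' perturbation applied (all other parameters untouched), and reports the
#' percent change of the per-gram benefit at the requested cell relative
#' to the unperturbed run.
#'
#' @param s A [scenario()] object.
#' @param spec A [sweep_spec()] object.
#' @param level,age_group,region Aggregation level and keys of the tracked
#'   benefit cell (defaults: national level).
#' @param period Period id of the tracked cell; defaults to the scenario's
#'   first period.
#' @param path Emission path of the tracked cell (default `"policy"`).
#' @return An object of class `bpt_sweep_result`: tibble with columns
#'   `parameter`, `scope`, `multiplier`, `baseline`, `perturbed`,
#'   `pct_change` (`100 * (perturbed - baseline) / baseline`).
#' @export
run_sweep <- function(s, spec, level = "national", age_group = NULL,
                      region = NULL, period = NULL, path = "policy") {
  stopifnot(inherits(s, "bpt_scenario"), inherits(spec, "bpthia_sweep_spec"))
  if (is.null(period)) period <- s$periods$id[1]
  base_report <- run_pipeline(s)
  baseline <- extract_bpt(base_report, level, age_group, region, period, path)
  if (baseline <= 0) {
    abort_validation("baseline BPT at the tracked cell must be positive.")
  }
  scope <- paste(c(spec$age_group, spec$period), collapse = "/")
  rows <- lapply(spec$multipliers, function(m) {
    pert <- run_pipeline(perturb_scenario(s, spec, m))
    v <- extract_bpt(pert, level, age_group, region, period, path)
    tibble::tibble(parameter = spec$parameter,
                   scope = if (nzchar(scope)) scope else "all",
                   multiplier = m, baseline = baseline, perturbed = v,
                   pct_change = 100 * (v - baseline) / baseline)
  })
  structure(dplyr::bind_rows(rows),
            class = c("bpt_sweep_result", class(dplyr::bind_rows(rows))))
}

#' Rank sweep results by impact
#'
#' Orders parameters by their maximum absolute percent change, descending;
#' ties are broken alphabetically by parameter name.
#'
#' @param results A list of [run_sweep()] results (or a single one).
#' @return Tibble with columns `parameter`, `scope`, `max_abs_pct_change`.
#' @export
tornado_summary <- function(results) {
  if (inherits(results, "bpt_sweep_result")) results <- list(results)
  if (length(results) == 0) abort_validation("results must be a nonempty list.")
  dplyr::bind_rows(lapply(results, tibble::as_tibble)) |>
    dplyr::summarise(max_abs_pct_change = max(abs(.data$pct_change)),
                     .by = c("parameter", "scope")) |>
    dplyr::arrange(dplyr::desc(.data$max_abs_pct_change), .data$parameter)
}
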