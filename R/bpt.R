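# Benefit-per-ton engine: per-gram benefit of emissions at group, region
# and national aggregation levels, net benefit of a reduction plan against
# the no-action baseline, and cumulative summaries.

emission_grams <- function(traj, path, region, period) {
  assert_cols(traj, c("region", "period", "path", "grams"), "trajectory")
  g <- traj$grams[traj$region == region & traj$period == period &
                    traj$path == path]
  if (length(g) == 0) {
    abort_validation(sprintf(
      "trajectory lacks cell (region %s, period %s, path %s).",
      region, period, path))
  }
  if (g[1] <= 0) {
    abort_validation(sprintf(
      "emissions are zero or negative at (region %s, period %s, path %s); per-gram benefit is undefined.",
      region, period, path))
  }
  g[1]
}

mdc_cell <- function(mdc, age_group, region, period) {
  assert_cols(mdc, c("age_group", "region", "period", "mdc"), "mdc")
  v <- mdc$mdc[mdc$age_group == age_group & mdc$region == region &
                 mdc$period == period]
  if (length(v) == 0) {
    abort_validation(sprintf("mdc lacks cell (%s, %s, %s).",
                             age_group, region, period))
  }
  v[1]
}

mdc_region_sum <- function(mdc, region, period) {
  assert_cols(mdc, c("age_group", "region", "period", "mdc"), "mdc")
  v <- mdc$mdc[mdc$region == region & mdc$period == period]
  if (length(v) == 0) {
    abort_validation(sprintf("mdc has no rows for (region %s, period %s).",
                             region, period))
  }
  sum(v)
}

#' Per-gram benefit for one age group
#'
#' `mdc[i, j, t] / E[j, t]`: the monetized expected cancer mortality of the
#' age group divided by the region's emissions on the given path.
#'
#' @param mdc Monetized-mortality tibble (`age_group`, `region`, `period`,
#'   `mdc` in USD).
#' @param traj Emission trajectory tibble (see [build_trajectory()]).
#' @param path `"policy"` or `"baseline"`.
#' @param age_group,region,period Cell keys.
#' @return USD per gram.
#' @export
bpt_group <- function(mdc, traj, path, age_group, region, period) {
  mdc_cell(mdc, age_group, region, period) /
    emission_grams(traj, path, region, period)
}

#' Per-gram benefit for a region (all age groups)
#'
#' Sums the region's monetized mortality over age groups before dividing by
#' the region's emissions.
#'
#' @inheritParams bpt_group
#' @return USD per gram.
#' @export
bpt_region <- function(mdc, traj, path, region, period) {
  mdc_region_sum(mdc, region, period) /
    emission_grams(traj, path, region, period)
}

#' National per-gram benefit
#'
#' Uses the designated national aggregate region's monetized mortality over
#' the national emission total. The national region is modelled first-class
#' (its own dose and risk), not as a sum of sub-regions.
#'
#' @inheritParams bpt_group
#' @param national Region id of the national aggregate.
#' @return USD per gram.
#' @export
bpt_national <- function(mdc, traj, path, period, national = "taiwan") {
  bpt_region(mdc, traj, path, national, period)
}

#' Net per-gram benefit of a reduction plan
#'
#' The benefit gap per gram between the policy and baseline emission paths
#' for the same monetized burden:
#' `mdc_agg * (1 / E_policy - 1 / E_baseline)`. Zero when the paths
#' coincide; strictly positive when policy emissions fall below baseline.
#'
#' @inheritParams bpt_group
#' @param level `"group"`, `"region"`, or `"national"`.
#' @param age_group Required when `level = "group"`.
#' @param region Required for `"group"` and `"region"` levels.
#' @param national Region id of the national aggregate (for
#'   `level = "national"`).
#' @return USD per gram.
#' @export
net_bpt <- function(mdc, traj, level = c("national", "region", "group"),
                    age_group = NULL, region = NULL, period,
                    national = "taiwan") {
  level <- match.arg(level)
  if (level == "national") region <- national
  if (is.null(region)) abort_validation("`region` is required at this level.")
  agg <- switch(level,
    group = {
      if (is.null(age_group)) abort_validation("`age_group` is required at group level.")
      mdc_cell(mdc, age_group, region, period)
    },
    region = ,
    national = mdc_region_sum(mdc, region, period)
  )
  e_pol <- emission_grams(traj, "policy", region, period)
  e_base <- emission_grams(traj, "baseline", region, period)
  agg * (1 / e_pol - 1 / e_base)
}

#' Full benefit-per-ton result table
#'
#' Computes the per-gram benefit for every (level, key, period) cell on the
#' policy and baseline paths plus their difference (`path = "net"`).
#'
#' @inheritParams bpt_group
#' @param national Region id of the national aggregate, or `NULL` to skip
#'   the national level.
#' @return Tibble with columns `level`, `age_group`, `region`, `period`,
#'   `path`, `usd_per_gram`.
#' @export
bpt_table <- function(mdc, traj, national = "taiwan") {
  assert_cols(mdc, c("age_group", "region", "period", "mdc"), "mdc")
  assert_cols(traj, c("region", "period", "path", "grams"), "trajectory")
  if (any(traj$grams <= 0)) {
    abort_validation("trajectory contains nonpositive emissions; per-gram benefit is undefined.")
  }
  wide <- tidyr::pivot_wider(traj, names_from = "path", values_from = "grams")

  grp <- dplyr::inner_join(mdc, wide, by = c("region", "period")) |>
    dplyr::mutate(level = "group",
                  policy = .data$mdc / .data$policy,
                  baseline = .data$mdc / .data$baseline)
  reg <- mdc |>
    dplyr::summarise(mdc = sum(.data$mdc), .by = c("region", "period")) |>
    dplyr::inner_join(wide, by = c("region", "period")) |>
    dplyr::mutate(level = "region", age_group = NA_character_,
                  policy = .data$mdc / .data$policy,
                  baseline = .data$mdc / .data$baseline)
  out <- dplyr::bind_rows(grp, reg)
  if (!is.null(national)) {
    nat <- reg |>
      dplyr::filter(.data$region == national) |>
      dplyr::mutate(level = "national")
    out <- dplyr::bind_rows(out, nat)
  }
  out |>
    dplyr::mutate(net = .data$policy - .data$baseline) |>
    dplyr::select("level", "age_group", "region", "period",
                  policy = "policy", baseline = "baseline", net = "net") |>
    tidyr::pivot_longer(c("policy", "baseline", "net"),
                        names_to = "path", values_to = "usd_per_gram")
}

#' Cumulative net benefit over a set of periods
#'
#' Arithmetic sum of the real-valued (unrounded) net per-gram benefit over
#' the listed periods at one aggregation level.
#'
#' @param result Output of [bpt_table()].
#' @param period_ids Character vector of period ids (may be empty).
#' @param level,age_group,region Cell keys as in [net_bpt()].
#' @return USD per gram.
#' @export
cumulative_net_bpt <- function(result, period_ids,
                               level = c("national", "region", "group"),
                               age_group = NULL, region = NULL) {
  level <- match.arg(level)
  assert_cols(result, c("level", "age_group", "region", "period", "path",
                        "usd_per_gram"), "result")
  if (length(period_ids) == 0) return(0)
  known <- unique(result$period)
  bad <- setdiff(period_ids, known)
  if (length(bad) > 0) {
    abort_validation(sprintf("unknown period id(s): %s.",
                             paste(bad, collapse = ", ")))
  }
  rows <- result[result$path == "net" & result$level == level &
                   result$period %in% period_ids, ]
  if (level == "group") {
    if (is.null(age_group)) abort_validation("`age_group` is required at group level.")
    rows <- rows[rows$age_group == age_group, ]
  }
  if (!is.null(region)) rows <- rows[rows$region == region, ]
  sum(rows$usd_per_gram)
}

#' Share of a part in a set of parts
#'
#' @param part A USD-per-gram amount.
#' @param whole_parts Numeric vector whose sum is the total (> 0).
#' @return `part / sum(whole_parts)`.
#' @examples
#' share_of_total(14087483, c(2697448, 14087483))
#' @export
share_of_total <- function(part, whole_parts) {
  assert_scalar_number(part, "part")
  total <- sum(whole_parts)
  if (!is.finite(total) || total <= 0) {
    abort_validation("sum of whole_parts must be positive.")
  }
  part / total
}
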