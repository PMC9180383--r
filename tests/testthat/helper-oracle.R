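# Shared fixtures and independent oracles.
#
# The oracle recomputes every pipeline quantity with plain nested loops and
# scalar arithmetic (no joins, no package internals) so that agreement is a
# genuine two-route check.

# A small handmade scenario: 2 sub-regions + national, 3 periods.
make_tiny_scenario <- function() {
  groups <- c("children", "working_age", "older")
  regions <- c("west", "east", "nation")
  periods <- c("p1", "p2", "p3")
  scenario(
    age_groups = tibble::tibble(id = groups, min_age = c(0, 15, 65),
                                max_age = c(14, 64, NA), label = groups),
    regions = tibble::tibble(id = regions, label = regions,
                             national = c(FALSE, FALSE, TRUE),
                             share = c(0.6, 0.4, NA)),
    periods = tibble::tibble(id = periods, start_year = c(2020, 2021, 2026),
                             end_year = c(2020, 2025, 2030)),
    exposure = tidyr::expand_grid(age_group = groups, region = regions) |>
      dplyr::mutate(ladd = c(1e-3, 2e-3, 3e-3, 4e-3, 5e-3, 6e-3,
                             7e-3, 8e-3, 9e-3)),
    coeffs = risk_coefficients(csf = 1e-4, mortality_risk = 0.2278),
    population = tidyr::expand_grid(age_group = groups, region = regions,
                                    period = periods) |>
      dplyr::mutate(count = 1e5 * seq_len(27)),
    vsl = tidyr::expand_grid(age_group = groups, period = periods) |>
      dplyr::mutate(vsl = 1e6 * seq_len(9)),
    trajectory = build_trajectory(
      c(west = 6, east = 4, nation = 10),
      list(trajectory_segment(1, 3, 1, 0.5)),
      tibble::tibble(id = periods, start_year = 1:3, end_year = 1:3)),
    provenance = "handmade test scenario"
  )
}

# Scalar lookup helpers over long tables (base R only).
lk2 <- function(df, value, i, j) {
  df[[value]][df$age_group == i & df$region == j]
}
lk3 <- function(df, value, i, j, t) {
  df[[value]][df$age_group == i & df$region == j & df$period == t]
}

# Brute-force mdc: ladd * csf * pop * mortality_risk * vsl, cell by cell.
oracle_mdc <- function(s) {
  out <- list()
  for (i in s$age_groups$id) for (j in s$regions$id) for (t in s$periods$id) {
    ladd <- lk2(s$exposure, "ladd", i, j)
    pop <- lk3(s$population, "count", i, j, t)
    vsl <- s$vsl$vsl[s$vsl$age_group == i & s$vsl$period == t]
    d <- ladd * s$coeffs$csf * pop * s$coeffs$mortality_risk
    if (!is.null(s$deaths_digits)) d <- round(d, s$deaths_digits)
    out[[paste(i, j, t)]] <- data.frame(age_group = i, region = j, period = t,
                                        mdc = d * vsl)
  }
  do.call(rbind, out)
}

# Brute-force per-gram benefit at every level/path, from an mdc data frame.
oracle_bpt <- function(mdc, traj, national) {
  grams <- function(j, t, p) {
    traj$grams[traj$region == j & traj$period == t & traj$path == p]
  }
  rows <- list()
  for (j in unique(mdc$region)) for (t in unique(mdc$period)) {
    for (p in c("policy", "baseline")) {
      e <- grams(j, t, p)
      tot <- 0
      for (i in unique(mdc$age_group)) {
        v <- lk3(mdc, "mdc", i, j, t)
        rows[[paste("g", i, j, t, p)]] <-
          data.frame(level = "group", age_group = i, region = j, period = t,
                     path = p, usd_per_gram = v / e)
        tot <- tot + v
      }
      rows[[paste("r", j, t, p)]] <-
        data.frame(level = "region", age_group = NA, region = j, period = t,
                   path = p, usd_per_gram = tot / e)
      if (j == national) {
        rows[[paste("n", j, t, p)]] <-
          data.frame(level = "national", age_group = NA, region = j,
                     period = t, path = p, usd_per_gram = tot / e)
      }
    }
  }
  do.call(rbind, rows)
}

# Compare a package bpt_table() against the oracle, cell by cell.
max_rel_err_vs_oracle <- function(s) {
  rep <- run_pipeline(s)
  national <- s$regions$id[s$regions$national]
  omdc <- oracle_mdc(s)
  obpt <- oracle_bpt(omdc, s$trajectory, national)
  got <- rep$tables$bpt
  errs <- numeric(0)
  for (k in seq_len(nrow(obpt))) {
    o <- obpt[k, ]
    sel <- got$level == o$level & got$region == o$region &
      got$period == o$period & got$path == o$path
    if (o$level == "group") sel <- sel & got$age_group == o$age_group
    v <- got$usd_per_gram[sel]
    denom <- max(abs(o$usd_per_gram), 1e-300)
    errs <- c(errs, abs(v - o$usd_per_gram) / denom)
  }
  max(errs)
}

taiwan_periods <- function() {
  c("2020", "2021-2025", "2026-2030", "2031-2035", "2036-2040", "2041-2045",
    "2046-2050", "2051-2055", "2056-2060", "2061-2065", "2066-2070")
}
phase_2021_2050 <- function() taiwan_periods()[2:7]
phase_2051_2070 <- function() taiwan_periods()[8:11]
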