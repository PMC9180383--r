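# Dose -> risk -> expected cases -> expected deaths.

test_that("cancer risk is dose times slope factor on the published cells", {
  coeffs <- risk_coefficients(csf = 1e-4, mortality_risk = 0.2278)
  exposure <- tidyr::expand_grid(
    age_group = c("working_age", "children", "older"),
    region = c("northern", "southern")) |>
    dplyr::mutate(ladd = c(1.52e-3, 1.56e-2, 0, 9.21e-3, 7.68e-4, 2.79e-2))
  risk <- compute_cancer_risk(exposure, coeffs)
  expect_equal(risk$risk,
               c(1.52e-7, 1.56e-6, 0, 9.21e-7, 7.68e-8, 2.79e-6),
               tolerance = 1e-12)
  # output grid identical to input grid
  expect_identical(risk[c("age_group", "region")],
                   exposure[c("age_group", "region")])
})

test_that("risk computation rejects incomplete grids and negative doses", {
  coeffs <- risk_coefficients(1e-4, 0.2278)
  holey <- tibble::tibble(age_group = c("children", "children", "older"),
                          region = c("a", "b", "a"), ladd = 1e-3)
  expect_error(compute_cancer_risk(holey, coeffs),
               class = "bpthia_validation_error")
  expect_error(compute_cancer_risk(holey, coeffs), "older.*b|b.*older")
  neg <- tibble::tibble(age_group = "children", region = "a", ladd = -1)
  expect_error(compute_cancer_risk(neg, coeffs), "negative",
               class = "bpthia_validation_error")
})

test_that("expected cases and deaths reproduce hand products from the published tables", {
  coeffs <- risk_coefficients(1e-4, 0.2278)
  risk <- tibble::tibble(
    age_group = c("children", "working_age"),
    region = c("southern", "taiwan"),
    risk = c(9.21e-7, 6.00e-7))
  pop <- tibble::tibble(
    age_group = c("children", "working_age"),
    region = c("southern", "taiwan"),
    period = "2020",
    count = c(820861, 16810525))
  er <- expected_at_risk(risk, pop, "2020")
  expect_equal(er$expected_cases, c(0.756013, 10.0863),
               tolerance = 1e-4)
  d <- expected_deaths(er, coeffs)
  expect_equal(d$deaths, c(0.172220, 2.2977), tolerance = 1e-4)
  # zero risk and zero mortality annihilate
  er0 <- expected_at_risk(dplyr::mutate(risk, risk = 0), pop, "2020")
  expect_true(all(er0$expected_cases == 0))
  d0 <- expected_deaths(er, risk_coefficients(1e-4, 0))
  expect_true(all(d0$deaths == 0))
})

test_that("a missing period is reported by id", {
  risk <- tibble::tibble(age_group = "children", region = "a", risk = 1e-7)
  pop <- tibble::tibble(age_group = "children", region = "a",
                        period = "p1", count = 1)
  expect_error(expected_at_risk(risk, pop, "p9"), "p9",
               class = "bpthia_validation_error")
})

test_that("mortality risk is the survival complement and rejects bad input", {
  expect_equal(mortality_risk_from_survival(0.7722), 0.2278)
  expect_equal(mortality_risk_from_survival(1), 0)
  expect_equal(mortality_risk_from_survival(0.5), 0.5)
  expect_error(mortality_risk_from_survival(1.2),
               class = "bpthia_validation_error")
  expect_error(mortality_risk_from_survival(-0.1),
               class = "bpthia_validation_error")
})

test_that("the chain is linear in dose and preserves the grid", {
  s <- make_tiny_scenario()
  coeffs <- s$coeffs
  r1 <- compute_cancer_risk(s$exposure, coeffs)
  r2 <- compute_cancer_risk(dplyr::mutate(s$exposure, ladd = 2 * ladd), coeffs)
  expect_equal(r2$risk, 2 * r1$risk)
  for (p in s$periods$id) {
    e1 <- expected_at_risk(r1, s$population, p)
    e2 <- expected_at_risk(r2, s$population, p)
    expect_equal(e2$expected_cases, 2 * e1$expected_cases)
    d1 <- expected_deaths(e1, coeffs); d2 <- expected_deaths(e2, coeffs)
    expect_equal(d2$deaths, 2 * d1$deaths)
    expect_setequal(paste(d1$age_group, d1$region),
                    paste(s$exposure$age_group, s$exposure$region))
  }
})

test_that("pipeline deaths equal the one-line brute-force product", {
  for (seed in c(11, 23)) {
    s <- generate_scenario(synth_config(n_regions = 3, n_periods = 4,
                                        seed = seed))
    risk <- compute_cancer_risk(s$exposure, s$coeffs)
    for (p in s$periods$id) {
      d <- expected_deaths(expected_at_risk(risk, s$population, p), s$coeffs)
      for (k in seq_len(nrow(d))) {
        ladd <- lk2(s$exposure, "ladd", d$age_group[k], d$region[k])
        pop <- lk3(s$population, "count", d$age_group[k], d$region[k], p)
        expected <- ladd * s$coeffs$csf * pop * s$coeffs$mortality_risk
        expect_equal(d$deaths[k], expected, tolerance = 1e-12)
      }
    }
  }
})
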