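# VSL transfer, deflation, discounted schedules, monetization.

tw_params <- function() {
  value_transfer_params(vsl_base = 11.79e6, earnings_elasticity = 0.2476,
                        wage_base = 1317.18, wage_target = 1385.64,
                        cpi_base = 98.93, cpi_target = 102.55,
                        exchange_rate = 31.807)
}

test_that("wage-elasticity transfer matches hand evaluation", {
  # 11.79e6 * (1 + 0.2476 * (1385.64-1317.18)/1317.18); pct wage change 5.1974%
  expect_equal(transfer_vsl_nominal(tw_params()), 11941724.67,
               tolerance = 1e-8)
  flat <- value_transfer_params(11.79e6, 0.2476, 1317.18, 1317.18,
                                98.93, 102.55)
  expect_equal(transfer_vsl_nominal(flat), 11.79e6)
  inert <- value_transfer_params(11.79e6, 0, 1317.18, 1385.64,
                                 98.93, 102.55)
  expect_equal(transfer_vsl_nominal(inert), 11.79e6)
})

test_that("CPI deflation matches hand evaluation", {
  expect_equal(deflate_vsl_real(tw_params(), 11.79e6), 11373814.72,
               tolerance = 1e-8)
  same <- value_transfer_params(11.79e6, 0.2476, 1317.18, 1385.64, 100, 100)
  expect_equal(deflate_vsl_real(same, 42), 42)
  half <- value_transfer_params(1, 0, 1, 1, 50, 100)
  expect_equal(deflate_vsl_real(half, 1), 0.5)
})

test_that("transfer and deflation compose as the product of their factors", {
  p <- tw_params()
  f_wage <- 1 + p$earnings_elasticity *
    (p$wage_target - p$wage_base) / p$wage_base
  f_cpi <- p$cpi_base / p$cpi_target
  expect_equal(deflate_vsl_real(p, transfer_vsl_nominal(p)),
               p$vsl_base * f_wage * f_cpi)
})

test_that("geometric discounting averages annual factors within a period", {
  periods <- tibble::tibble(id = "2021-2025", start_year = 2021,
                            end_year = 2025)
  sch <- build_vsl_schedule(c(children = 100), periods,
                            discount_spec(0.02, 2020, "geometric_annual"))
  # (1/5) * sum_{k=1..5} 1.02^-k = 0.942692
  expect_equal(sch$vsl, 94.2692, tolerance = 1e-6)
  flat <- build_vsl_schedule(c(children = 100), periods,
                             discount_spec(0, 2020, "geometric_annual"))
  expect_equal(flat$vsl, 100)
})

test_that("the fixture convention passes a supplied schedule through verbatim", {
  fx <- taiwan_dioxin_scenario()
  sch <- build_vsl_schedule(NULL, fx$periods,
                            discount_spec(0.02, 2020, "fixture"),
                            schedule = fx$vsl)
  expect_identical(sch, fx$vsl)
  expect_equal(sch$vsl[sch$age_group == "children" &
                         sch$period == "2021-2025"], 2167689)
  expect_error(build_vsl_schedule(NULL, fx$periods,
                                  discount_spec(0.02, 2020, "fixture")),
               class = "bpthia_validation_error")
  expect_error(discount_spec(0.02, 2020, "quarterly"), "geometric_annual")
})

test_that("monetization reproduces the published national 2020 cells", {
  sch <- tibble::tibble(age_group = c("working_age", "children"),
                        period = c("2020", "2020"),
                        vsl = c(12326614, 2194866))
  d <- tibble::tibble(age_group = c("working_age", "children"),
                      region = "taiwan", period = "2020",
                      deaths = c(2.2977, 0.172220))
  mdc <- monetize_deaths(d, sch)
  expect_equal(mdc$mdc[1], 28322862, tolerance = 1e-4)
  expect_equal(mdc$mdc[2], 377956, tolerance = 2e-4)
  zero <- monetize_deaths(dplyr::mutate(d, deaths = 0), sch)
  expect_true(all(zero$mdc == 0))
})

test_that("monetization names a missing schedule cell", {
  d <- tibble::tibble(age_group = "older", region = "x", period = "p2",
                      deaths = 1)
  sch <- tibble::tibble(age_group = "older", period = "p1", vsl = 1e6)
  expect_error(monetize_deaths(d, sch), "older.*p2",
               class = "bpthia_validation_error")
})

test_that("monetization is bilinear in deaths and VSL", {
  s <- make_tiny_scenario()
  risk <- compute_cancer_risk(s$exposure, s$coeffs)
  d <- expected_deaths(expected_at_risk(risk, s$population, "p2"), s$coeffs)
  m1 <- monetize_deaths(d, s$vsl)
  m2 <- monetize_deaths(dplyr::mutate(d, deaths = 3 * deaths), s$vsl)
  expect_equal(m2$mdc, 3 * m1$mdc)
  vsl_up <- dplyr::mutate(s$vsl,
                          vsl = ifelse(age_group == "older", 2 * vsl, vsl))
  m3 <- monetize_deaths(d, vsl_up)
  old <- m1$age_group == "older"
  expect_equal(m3$mdc[old], 2 * m1$mdc[old])
  expect_equal(m3$mdc[!old], m1$mdc[!old])
})
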