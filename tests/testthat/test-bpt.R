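# Per-gram benefit at all aggregation levels, net benefit, cumulative sums.

fx <- taiwan_dioxin_scenario()
mdc_pub <- fx$reference$mdc
traj <- fx$trajectory

test_that("group-level BPT is the published monetized value over emissions", {
  expect_equal(bpt_group(mdc_pub, traj, "baseline", "children", "taiwan",
                         "2021-2025"), 447845 / 57.8, tolerance = 1e-10)
  expect_equal(bpt_group(mdc_pub, traj, "policy", "children", "taiwan",
                         "2021-2025"), 447845 / 52.9833, tolerance = 1e-10)
  zero <- dplyr::mutate(mdc_pub, mdc = 0)
  expect_equal(bpt_group(zero, traj, "policy", "children", "taiwan",
                         "2021-2025"), 0)
})

test_that("region-level BPT sums age groups before dividing", {
  expect_equal(bpt_region(mdc_pub, traj, "policy", "northern", "2020"),
               (47848 + 3191360 + 759491) / 5.7628, tolerance = 1e-10)
  expect_equal(bpt_region(mdc_pub, traj, "policy", "southern", "2020"),
               (377956 + 20398082 + 17167073) / 31.9743, tolerance = 1e-10)
})

test_that("national BPT reproduces the published headline and later periods", {
  expect_equal(bpt_national(mdc_pub, traj, "policy", "2020"),
               837915, tolerance = 2 / 837915)
  expect_equal(bpt_national(mdc_pub, traj, "baseline", "2021-2025"),
               49771262 / 57.8, tolerance = 1e-10)
})

test_that("division by zero emissions is guarded", {
  bad <- dplyr::mutate(traj, grams = ifelse(region == "taiwan" &
                                              period == "2020", 0, grams))
  expect_error(bpt_national(mdc_pub, bad, "policy", "2020"),
               class = "bpthia_validation_error")
})

test_that("net BPT is the reciprocal-emission-difference formula", {
  expect_equal(net_bpt(mdc_pub, traj, "group", "children", period = "2021-2025",
                       region = "taiwan"),
               447845 * (1 / 52.9833 - 1 / 57.8), tolerance = 1e-10)
  expect_equal(net_bpt(mdc_pub, traj, "national", period = "2021-2025"),
               78282, tolerance = 2 / 78282)
  # 2020: paths coincide, net is zero
  expect_equal(net_bpt(mdc_pub, traj, "national", period = "2020"), 0)
})

test_that("the full published net-BPT table is reproduced", {
  result <- bpt_table(mdc_pub, traj, national = "taiwan")
  pub <- fx$reference$net_bpt
  got <- result |>
    dplyr::filter(path == "net", level == "group") |>
    dplyr::inner_join(dplyr::rename(pub, pub = usd_per_gram),
                      by = c("age_group", "region", "period"))
  expect_equal(nrow(got), nrow(pub))
  # Taiwan-level cells at print-rounding tolerance
  tw <- got[got$region == "taiwan", ]
  expect_true(all(abs(tw$usd_per_gram - tw$pub) <= 1e-4 * tw$pub + 2))
  # full grid: a few published per-gram cells were printed from less-rounded
  # monetized values, so the band is slightly wider
  expect_true(all(abs(got$usd_per_gram - got$pub) <= 2e-3 * got$pub + 2))
})

test_that("cumulative net BPT reproduces the published phase totals", {
  result <- bpt_table(mdc_pub, traj, national = "taiwan")
  expect_equal(cumulative_net_bpt(result, phase_2021_2050(), "national"),
               2697448, tolerance = 1e-5)
  expect_equal(cumulative_net_bpt(result, phase_2051_2070(), "region",
                                  region = "central"),
               4225620, tolerance = 1e-5)
  expect_equal(cumulative_net_bpt(result, character(0), "national"), 0)
  expect_error(cumulative_net_bpt(result, "2080-2085", "national"),
               "2080-2085", class = "bpthia_validation_error")
})

test_that("phase shares divide as published", {
  result <- bpt_table(mdc_pub, traj, national = "taiwan")
  early <- cumulative_net_bpt(result, phase_2021_2050(), "national")
  late <- cumulative_net_bpt(result, phase_2051_2070(), "national")
  expect_equal(share_of_total(late, c(early, late)), 0.8393,
               tolerance = 1e-4)
  expect_equal(share_of_total(early, c(early, late)), 0.1607,
               tolerance = 1e-3)
  expect_equal(share_of_total(5, 5), 1)
  expect_error(share_of_total(1, c(0, 0)), class = "bpthia_validation_error")
})

test_that("BPT is homogeneous of degree -1 in emissions and net is additive and monotone", {
  s <- generate_scenario(synth_config(n_regions = 3, n_periods = 5, seed = 5))
  rep1 <- run_pipeline(s)
  mdc <- rep1$tables$mdc
  t1 <- bpt_table(mdc, s$trajectory, national = "national")
  scaled <- dplyr::mutate(s$trajectory, grams = 3 * grams)
  t2 <- bpt_table(mdc, scaled, national = "national")
  expect_equal(t2$usd_per_gram, t1$usd_per_gram / 3)

  # additivity: region net equals the sum of its group nets
  per_group <- t1 |>
    dplyr::filter(path == "net", level == "group") |>
    dplyr::summarise(s = sum(usd_per_gram), .by = c(region, period))
  per_region <- t1 |>
    dplyr::filter(path == "net", level == "region") |>
    dplyr::select(region, period, r = usd_per_gram)
  j <- dplyr::inner_join(per_group, per_region, by = c("region", "period"))
  expect_equal(j$s, j$r)

  # monotonicity: lowering policy emissions below baseline raises net BPT
  p <- s$periods$id[3]
  r <- s$regions$id[1]
  base_net <- net_bpt(mdc, s$trajectory, "region", region = r, period = p)
  deeper <- dplyr::mutate(s$trajectory,
                          grams = ifelse(path == "policy" & region == r &
                                           period == p, grams * 0.5, grams))
  expect_gt(net_bpt(mdc, deeper, "region", region = r, period = p), base_net)
  expect_gte(base_net, 0)
})

test_that("every aggregation level matches the brute-force loop oracle", {
  for (seed in c(2, 9)) {
    s <- generate_scenario(synth_config(n_regions = 2, n_periods = 3,
                                        seed = seed))
    expect_lt(max_rel_err_vs_oracle(s), 1e-12)
  }
})
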