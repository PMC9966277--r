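make_expected <- function(years = 2020:2024, rate = 100, count = 1e6) {
  inc <- tibble::tibble(sex = c("male", "female"),
                        age_group = "50-54", rate = rate)
  pop <- tidyr::crossing(year = years, inc[, c("sex", "age_group")])
  pop$count <- count
  expected_cases(inc, pop)
}

test_that("expected cases are rate times population over 100,000", {
  exp <- make_expected()
  expect_equal(unique(exp$expected_cases), 1000)
  # zero population year gives zero cases
  inc <- tibble::tibble(sex = "male", age_group = "50-54", rate = 100)
  pop <- tibble::tibble(year = 2020:2021, sex = "male",
                        age_group = "50-54", count = c(0, 5e5))
  out <- expected_cases(inc, pop)
  expect_equal(out$expected_cases, c(0, 500))
})

test_that("expected cases are linear in rates (brute-force recomputation)", {
  set.seed(12)
  inc <- generate_incidence()
  pop <- constant_population(years = 2020:2023)
  e1 <- expected_cases(inc, pop)
  inc2 <- inc
  inc2$rate <- 2 * inc2$rate
  e2 <- expected_cases(inc2, pop)
  expect_equal(e2$expected_cases, 2 * e1$expected_cases, tolerance = 1e-12)
  # explicit per-row recomputation
  merged <- merge(pop, inc, by = c("sex", "age_group"))
  brute <- sum(merged$rate * merged$count) / 1e5
  expect_equal(sum(e1$expected_cases), brute, tolerance = 1e-9)
})

test_that("misaligned strata are rejected with the missing key", {
  inc <- tibble::tibble(sex = "male", age_group = "50-54", rate = 10)
  pop <- tibble::tibble(year = 2020, sex = "male",
                        age_group = c("50-54", "55-59"), count = 1000)
  expect_error(expected_cases(inc, pop), "55-59")
})

test_that("prevented cases multiply, accumulate, and bound correctly", {
  exp <- make_expected(2020:2029)
  pifs <- tidyr::crossing(year = 2020:2029, sex = c("male", "female"),
                          age_group = "50-54", scenario = "s",
                          lag_years = 9)
  pifs$pif <- 0.1
  proj <- prevented_cases(exp, pifs)
  expect_equal(unique(proj$prevented), 100)
  expect_true(all(proj$prevented <= proj$expected_cases))
  # constant PIF p, constant E over y years: cumulative = p * E * y
  final <- proj[proj$year == 2029, ]
  expect_equal(unique(final$cumulative_prevented), 0.1 * 1000 * 10,
               tolerance = 1e-12)
  # PIF 0 everywhere gives an all-zero table
  pifs0 <- pifs
  pifs0$pif <- 0
  proj0 <- prevented_cases(exp, pifs0)
  expect_true(all(proj0$prevented == 0) && all(proj0$cumulative_prevented == 0))
})

test_that("a missing PIF for a productive stratum is an error, not a zero", {
  exp <- make_expected(2020:2021)
  pifs <- tibble::tibble(year = 2020:2021, sex = "male",
                         age_group = "50-54", scenario = "s",
                         lag_years = 9, pif = 0.1)
  expect_error(prevented_cases(exp, pifs), "female")
})

test_that("cumulative prevented equals the sum of annual prevented", {
  tm <- temporal_model(2020, 1, 9, horizon = 2020:2050)
  rec <- lognormal_records(200, mu = log(40), sigma = 0.75)
  traj <- yearly_pif_trajectory(rec, scenario("e", "processed_meat",
                                              "eliminate"),
                                list(rf_processed()), tm)
  exp <- make_expected(2020:2050)
  pifs <- tidyr::crossing(sex = c("male", "female"),
                          traj[, c("year", "pif")])
  pifs$age_group <- "50-54"
  pifs$scenario <- "e"
  pifs$lag_years <- 9
  proj <- prevented_cases(exp, pifs)
  for (sx in c("male", "female")) {
    sub <- proj[proj$sex == sx, ]
    expect_equal(max(sub$cumulative_prevented), sum(sub$prevented),
                 tolerance = 1e-6)
  }
})

test_that("summary reproduces report percentages and additivity", {
  expect_equal(prevented_pct(145291, 1208329), 12.0)
  expect_equal(prevented_pct(0, 1208329), 0.0)
  exp <- make_expected(2020:2024)
  pifs <- tidyr::crossing(year = 2020:2024, sex = c("male", "female"),
                          age_group = "50-54", scenario = c("a", "b"),
                          lag_years = c(5, 9))
  pifs$pif <- ifelse(pifs$scenario == "a", 0.05, 0.12)
  summ <- summarize_projection(prevented_cases(exp, pifs))
  # per-sex percentage computed from unrounded totals
  expect_equal(summ$pct_prevented[summ$scenario == "a"][1], 5.0)
  expect_equal(summ$pct_prevented[summ$scenario == "b"][1], 12.0)
  # sex-specific totals add to the combined row
  for (lg in c(5, 9)) for (sc in c("a", "b")) {
    rows <- summ[summ$lag_years == lg & summ$scenario == sc, ]
    expect_equal(rows$prevented[rows$sex == "both"],
                 sum(rows$prevented[rows$sex != "both"]), tolerance = 1e-9)
  }
  # report layout: one # / % pair per scenario within each sex block
  txt <- format_summary_table(summ)
  expect_true(any(grepl("^Lag time: 5 years", txt)))
  expect_true(any(grepl("scenario\\s+#\\s+%", txt)))
  expect_equal(sum(grepl("^    a\\s", txt)), 6)  # 2 lags x 3 sex rows
})

test_that("annual series aggregates sexes and accumulates", {
  exp <- make_expected(2020:2022)
  pifs <- tidyr::crossing(year = 2020:2022, sex = c("male", "female"),
                          age_group = "50-54", scenario = "s", lag_years = 9)
  pifs$pif <- 0.1
  ser <- annual_series(prevented_cases(exp, pifs))
  expect_equal(ser$prevented, rep(200, 3))
  expect_equal(ser$cumulative_prevented, c(200, 400, 600))
})
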