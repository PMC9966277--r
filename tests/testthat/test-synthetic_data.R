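test_that("lognormal fit matches the closed-form quantile solution", {
  fit <- fit_lognormal_from_quantiles(47, 78)
  expect_equal(fit$mu, log(47), tolerance = 1e-12)
  expect_equal(fit$sigma, log(78 / 47) / stats::qnorm(0.75),
               tolerance = 1e-12)
  expect_equal(fit$sigma, 0.7510, tolerance = 1e-3)
  # implied mean diagnostic lands near the printed 61 g/day margin
  expect_equal(fit$implied_mean, exp(fit$mu + fit$sigma^2 / 2),
               tolerance = 1e-12)
  expect_equal(fit$implied_mean, 62.3, tolerance = 0.01)
  fit2 <- fit_lognormal_from_quantiles(26, 60)
  expect_equal(fit2$sigma, log(60 / 26) / stats::qnorm(0.75),
               tolerance = 1e-12)
  expect_equal(fit2$sigma, 1.2400, tolerance = 1e-3)
  # degenerate point mass
  expect_equal(fit_lognormal_from_quantiles(26, 26)$sigma, 0)
  expect_error(fit_lognormal_from_quantiles(47, 40), ">=")
  expect_error(fit_lognormal_from_quantiles(0, 40), "zero_mass")
})

test_that("zero-inflated fit still matches the printed quantiles", {
  zm <- 0.1
  fit <- fit_lognormal_from_quantiles(47, 78, zero_mass = zm)
  # mixture quantiles: P(X <= q) = zm + (1 - zm) * plnorm(q)
  expect_equal(zm + (1 - zm) * stats::plnorm(47, fit$mu, fit$sigma), 0.5,
               tolerance = 1e-12)
  expect_equal(zm + (1 - zm) * stats::plnorm(78, fit$mu, fit$sigma), 0.75,
               tolerance = 1e-12)
})

test_that("generate_survey is reproducible and honors degenerate fits", {
  fits <- tibble::tibble(sex = "male", age_group = "50-54",
                         factor = c("red_meat", "processed_meat"),
                         mu = log(c(26, 33)), sigma = c(0, 0.8),
                         zero_mass = 0)
  s1 <- generate_survey(fits, 200, seed = 3)
  s2 <- generate_survey(fits, 200, seed = 3)
  expect_identical(s1, s2)
  expect_equal(s1$red_meat, rep(26, 200))  # sigma 0 point mass
  expect_true(all(s1$processed_meat >= 0))
  s3 <- generate_survey(fits, 200, seed = 4)
  expect_false(identical(s1$processed_meat, s3$processed_meat))
})

test_that("generated intakes recover the fitted quantiles and tail", {
  fit <- fit_lognormal_from_quantiles(47, 78)
  fits <- tibble::tibble(sex = "male", age_group = "all",
                         factor = "processed_meat", mu = fit$mu,
                         sigma = fit$sigma, zero_mass = 0)
  sv <- generate_survey(fits, 100000, seed = 17)
  x <- sv$processed_meat
  expect_equal(stats::median(x), 47, tolerance = 0.03)
  expect_equal(unname(stats::quantile(x, 0.75)), 78, tolerance = 0.03)
  # round-trip parameter recovery within 2% relative error
  refit <- fit_lognormal_from_quantiles(stats::median(x),
                                        unname(stats::quantile(x, 0.75)))
  expect_equal(refit$mu, fit$mu, tolerance = 0.02)
  expect_equal(refit$sigma, fit$sigma, tolerance = 0.02)
  # heavy right tail: p99/median ratio near the printed 242/47
  ratio <- unname(stats::quantile(x, 0.99)) / stats::median(x)
  expect_equal(ratio, 242 / 47, tolerance = 0.3)
})

test_that("survey copula couples the two meat types by rank correlation", {
  fits <- default_intake_fits()
  sv <- generate_survey(fits[fits$sex == "male" &
                               fits$age_group == "50-54", ],
                        20000, seed = 8, rank_correlation = 0.3)
  rho <- stats::cor(sv$red_meat, sv$processed_meat, method = "spearman")
  expect_equal(rho, 0.3, tolerance = 0.1)
  sv0 <- generate_survey(fits[fits$sex == "male" &
                                fits$age_group == "50-54", ],
                         20000, seed = 8, rank_correlation = 0)
  expect_lt(abs(stats::cor(sv0$red_meat, sv0$processed_meat,
                           method = "spearman")), 0.05)
})

test_that("default fits cover every adult stratum for both factors", {
  fits <- default_intake_fits()
  expect_setequal(unique(fits$age_group), age_bands(adult_only = TRUE))
  expect_setequal(unique(fits$sex), c("male", "female"))
  expect_equal(nrow(fits), 2 * 13 * 2)
  # 80+ carries the 75-79 fit forward
  f80 <- fits[fits$age_group == "80+", ]
  f75 <- fits[fits$age_group == "75-79", ]
  expect_equal(f80$mu, f75$mu)
  expect_equal(f80$sigma, f75$sigma)
  # male locations sit above female locations (higher printed means)
  wide <- merge(fits[fits$sex == "male", c("age_group", "factor", "mu")],
                fits[fits$sex == "female", c("age_group", "factor", "mu")],
                by = c("age_group", "factor"))
  expect_true(all(wide$mu.x > wide$mu.y))
})

test_that("synthetic incidence follows the exponential age gradient", {
  inc <- generate_incidence(base_rate = 10, reference_group = "40-44",
                            doubling_years = 10, male_female_ratio = 1)
  r40 <- inc$rate[inc$sex == "female" & inc$age_group == "40-44"]
  r70 <- inc$rate[inc$sex == "female" & inc$age_group == "70-74"]
  expect_equal(r40, 10, tolerance = 1e-12)
  expect_equal(r70, 80, tolerance = 1e-12)
  # zero base rate gives an all-zero table; sex ratio scales males
  expect_true(all(generate_incidence(base_rate = 0)$rate == 0))
  inc2 <- generate_incidence(male_female_ratio = 1.3)
  m <- inc2$rate[inc2$sex == "male"]
  f <- inc2$rate[inc2$sex == "female"]
  expect_equal(m, 1.3 * f, tolerance = 1e-12)
  expect_error(generate_incidence(doubling_years = -1), "positive")
})

test_that("default rates and population give a plausible national burden", {
  # calibration check: order of magnitude of a 31-year national projection
  total <- sum(expected_cases(generate_incidence(),
                              generate_population())$expected_cases)
  expect_gt(total, 1.5e6)
  expect_lt(total, 3e6)
})

test_that("cohort-drift projection conserves persons through flows", {
  start <- default_start_counts()
  pop <- generate_population(start, years = 2020:2030, survival = 1,
                             entry = 0)
  totals <- as.numeric(tapply(pop$count, pop$year, sum))
  expect_equal(totals, rep(sum(start$count), 11), tolerance = 1e-9)
  # survival 0 in the open band: its next count is the inflow from below
  pop0 <- generate_population(start, years = 2020:2021,
                              survival = c(rep(1, 13), 0), entry = 0)
  inflow <- start$count[start$sex == "male" & start$age_group == "75-79"] / 5
  got <- pop0$count[pop0$year == 2021 & pop0$sex == "male" &
                      pop0$age_group == "80+"]
  expect_equal(got, inflow, tolerance = 1e-9)
  expect_error(generate_population(start, survival = rep(2, 14)), "survival")
})

test_that("constant_population repeats the counts for every year", {
  pop <- constant_population(years = 2020:2022)
  expect_equal(nrow(pop), 3 * nrow(default_start_counts()))
  totals <- as.numeric(tapply(pop$count, pop$year, sum))
  expect_equal(diff(totals), c(0, 0))
})
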