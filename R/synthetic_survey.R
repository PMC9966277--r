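#' Published intake summary statistics for German adults
#'
#' Summary statistics (grams/day) of red and processed meat intake among
#' German adults aged 18-79, as published from the nationally representative
#' DEGS1 survey (2008-2011): minimum, quartiles, mean, and 99th percentile,
#' by sex and by 5-year age band (sexes combined). These printed margins are
#' the calibration targets of the synthetic survey generator; the underlying
#' microdata are not redistributable.
#'
#' @return A tibble with columns `factor` (`red_meat` / `processed_meat`),
#'   `stratum_type` (`sex`, `overall`, `age`), `stratum`, `min`, `q1`,
#'   `median`, `mean`, `q3`, `p99`.
#' @export
intake_reference_summaries <- function() {
  strata <- c("males", "females", "overall", "18-24", "25-29", "30-34",
              "35-39", "40-44", "45-49", "50-54", "55-59", "60-64",
              "65-69", "70-74", "75-79")
  stype <- c("sex", "sex", "overall", rep("age", 12L))
  red <- tibble::tibble(
    factor = "red_meat", stratum_type = stype, stratum = strata,
    min = 0,
    q1 = c(11, 11, 11, 11, 11, 11, 13, 11, 11, 11, 11, 11, 11, 11, 11),
    median = rep(26, 15L),
    mean = c(47, 29, 38, 45, 39, 39, 41, 38, 37, 37, 33, 35, 34, 29, 28),
    q3 = c(60, 30, 60, 60, 60, 60, 60, 60, 60, 60, 60, 60, 60, 30, 30),
    p99 = c(240, 120, 189, 240, 240, 240, 240, 120, 120, 120, 120, 120,
            120, 120, 120)
  )
  processed <- tibble::tibble(
    factor = "processed_meat", stratum_type = stype, stratum = strata,
    min = 0,
    q1 = c(24, 11, 16, 19, 16, 18, 19, 17, 17, 17, 17, 14, 14, 15, 12),
    median = c(47, 23, 33, 42, 37, 38, 40, 36, 35, 34, 32, 27, 29, 27, 26),
    mean = c(61, 32, 46, 55, 50, 55, 54, 47, 47, 46, 44, 39, 39, 35, 36),
    q3 = c(78, 42, 59, 74, 66, 66, 73, 63, 62, 60, 55, 52, 54, 48, 45),
    p99 = c(242, 169, 220, 239, 199, 219, 244, 213, 236, 199, 511, 169,
            172, 147, 171)
  )
  dplyr::bind_rows(red, processed)
}

#' Fit a lognormal intake distribution from published quantiles
#'
#' Matches a (possibly zero-inflated) lognormal to a printed median and third
#' quartile. With `zero_mass = 0` the closed form is `mu = log(median)` and
#' `sigma = log(q3 / median) / qnorm(0.75)`; with a positive zero mass the
#' corresponding conditional quantile levels are used instead. The implied
#' arithmetic mean `(1 - zero_mass) * exp(mu + sigma^2 / 2)` is attached as a
#' diagnostic to compare against a printed mean; it is not a fitting target.
#'
#' @param median Printed median intake in grams/day (> 0).
#' @param q3 Printed third quartile in grams/day (>= median).
#' @param zero_mass Probability of exactly zero intake, in \[0, 0.5).
#'   Default 0.
#' @return An object of class `lognormal_fit` with fields `mu`, `sigma`,
#'   `zero_mass`, and `implied_mean`.
#' @examples
#' fit_lognormal_from_quantiles(47, 78)  # male processed meat margin
#' @export
fit_lognormal_from_quantiles <- function(median, q3, zero_mass = 0) {
  if (!is.numeric(median) || length(median) != 1L || !is.finite(median) ||
      median <= 0) {
    stop("`median` must be a single positive number; for a stratum with a ",
         "zero median use `zero_mass` on a positive-intake subgroup instead",
         call. = FALSE)
  }
  if (!is.numeric(q3) || length(q3) != 1L || !is.finite(q3) || q3 < median) {
    stop("`q3` must be a single number >= `median`", call. = FALSE)
  }
  if (!is.numeric(zero_mass) || length(zero_mass) != 1L || zero_mass < 0 ||
      zero_mass >= 0.5) {
    stop("`zero_mass` must lie in [0, 0.5)", call. = FALSE)
  }
  z_med <- stats::qnorm((0.5 - zero_mass) / (1 - zero_mass))
  z_q3 <- stats::qnorm((0.75 - zero_mass) / (1 - zero_mass))
  sigma <- log(q3 / median) / (z_q3 - z_med)
  mu <- log(median) - sigma * z_med
  structure(
    list(mu = mu, sigma = sigma, zero_mass = zero_mass,
         implied_mean = (1 - zero_mass) * exp(mu + sigma^2 / 2)),
    class = "lognormal_fit"
  )
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf(
    "<lognormal_fit> mu %.4f, sigma %.4f, zero mass %.3g, implied mean %.1f g/day\n",
    x$mu, x$sigma, x$zero_mass, x$implied_mean))
  invisible(x)
}

#' Age bands used in projections
#'
#' The fixed ordered list of age groups: an under-18 band (no intake data;
#' the pipeline assigns it zero impact), the survey bands 18-24 through
#' 75-79, and an open-ended 80+ band whose intake distribution is carried
#' forward from 75-79.
#'
#' @param adult_only If `TRUE`, only the bands with intake data (18-24
#'   through 75-79, plus 80+).
#' @return Character vector of age-band labels, in ascending order.
#' @export
age_bands <- function(adult_only = FALSE) {
  adult <- c("18-24", "25-29", "30-34", "35-39", "40-44", "45-49",
             "50-54", "55-59", "60-64", "65-69", "70-74", "75-79", "80+")
  if (adult_only) adult else c("0-17", adult)
}

#' Sex-by-age lognormal fits calibrated to the published margins
#'
#' The published table gives sex margins and age margins (sexes combined)
#' separately. The default synthesis fits each age band's lognormal from its
#' median and third quartile, then shifts its location by the sex-to-overall
#' ratio of printed means (equal printed medians make medians uninformative
#' for red meat), so that generated sex margins approximate the printed
#' ones. 80+ reuses the 75-79 fit.
#'
#' @param summaries Reference summary tibble; default
#'   [intake_reference_summaries()].
#' @param zero_mass Shared zero-intake probability for all strata. Default 0.
#' @return A tibble with columns `sex`, `age_group`, `factor`, `mu`, `sigma`,
#'   `zero_mass`.
#' @export
default_intake_fits <- function(summaries = intake_reference_summaries(),
                                zero_mass = 0) {
  out <- list()
  for (fac in unique(summaries$factor)) {
    s <- summaries[summaries$factor == fac, ]
    overall_mean <- s$mean[s$stratum == "overall"]
    for (sex in c("male", "female")) {
      margin <- s[s$stratum == ifelse(sex == "male", "males", "females"), ]
      shift <- log(margin$mean / overall_mean)
      for (ag in age_bands(adult_only = TRUE)) {
        src <- if (ag == "80+") "75-79" else ag
        row <- s[s$stratum == src, ]
        fit <- fit_lognormal_from_quantiles(row$median, row$q3, zero_mass)
        out[[length(out) + 1L]] <- tibble::tibble(
          sex = sex, age_group = ag, factor = fac,
          mu = fit$mu + shift, sigma = fit$sigma, zero_mass = zero_mass)
      }
    }
  }
  dplyr::bind_rows(out)
}

# Inverse CDF of a zero-inflated lognormal, u ~ Uniform(0,1).
qzilnorm <- function(u, mu, sigma, zero_mass) {
  ifelse(u < zero_mass, 0,
         stats::qlnorm((u - zero_mass) / (1 - zero_mass), mu, sigma))
}

#' Generate a synthetic exposure survey
#'
#' Draws reproducible individual intake records from per-stratum lognormal
#' fits. Within an individual, the intakes of the different factors are
#' coupled through a Gaussian copula with the requested Spearman rank
#' correlation (the normal-score correlation is `2 * sin(pi * rho / 6)`), so
#' heavy red-meat eaters tend also to be heavy processed-meat eaters.
#'
#' @param fits Tibble of fits as produced by [default_intake_fits()]:
#'   columns `sex`, `age_group`, `factor`, `mu`, `sigma`, `zero_mass`.
#'   Every (sex, age_group) stratum must provide a row for each factor.
#' @param n_per_stratum Number of records per (sex, age_group) stratum.
#' @param seed Integer RNG seed; same seed and fits give identical output.
#' @param rank_correlation Spearman correlation between the factors within an
#'   individual, in (-1, 1). Default 0.3.
#' @return A tibble of exposure records: `id`, `sex`, `age_group`, one
#'   grams/day column per factor, and `weight` (all 1).
#' @export
generate_survey <- function(fits, n_per_stratum, seed,
                            rank_correlation = 0.3) {
  stopifnot(is.data.frame(fits), n_per_stratum >= 1L)
  if (abs(rank_correlation) >= 1) {
    stop("`rank_correlation` must lie in (-1, 1)", call. = FALSE)
  }
  needed <- c("sex", "age_group", "factor", "mu", "sigma", "zero_mass")
  missing <- setdiff(needed, names(fits))
  if (length(missing)) {
    stop(sprintf("`fits` lacks column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  factors <- unique(fits$factor)
  strata <- unique(fits[, c("sex", "age_group")])
  rho <- 2 * sin(pi * rank_correlation / 6)
  set.seed(as.integer(seed))
  out <- vector("list", nrow(strata))
  next_id <- 1L
  for (i in seq_len(nrow(strata))) {
    sx <- strata$sex[i]
    ag <- strata$age_group[i]
    block <- fits[fits$sex == sx & fits$age_group == ag, ]
    if (nrow(block) != length(factors)) {
      stop(sprintf("stratum (%s, %s) lacks a fit for every factor", sx, ag),
           call. = FALSE)
    }
    n <- as.integer(n_per_stratum)
    # shared latent normal + factor-specific noise gives normal-score
    # correlation rho between any two factors (flip one score if rho < 0)
    common <- stats::rnorm(n)
    rec <- tibble::tibble(id = paste0("r", next_id - 1L + seq_len(n)),
                          sex = sx, age_group = ag)
    for (fac in factors) {
      row <- block[block$factor == fac, ]
      flip <- if (rho < 0 && fac != factors[1L]) -1 else 1
      z <- flip * sqrt(abs(rho)) * common +
        sqrt(1 - abs(rho)) * stats::rnorm(n)
      u <- stats::pnorm(z)
      rec[[fac]] <- qzilnorm(u, row$mu, row$sigma, row$zero_mass)
    }
    rec$weight <- 1
    next_id <- next_id + n
    out[[i]] <- rec
  }
  dplyr::bind_rows(out)
}
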