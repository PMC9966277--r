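# Shared fixtures for the test suite. Everything is built in code.

rf_red <- function() risk_factor("red_meat", 1.12, 100)
rf_processed <- function() risk_factor("processed_meat", 1.16, 50)

# A tiny deterministic exposure table covering two strata.
tiny_records <- function() {
  tibble::tibble(
    id = paste0("r", 1:6),
    sex = rep(c("male", "female"), each = 3),
    age_group = rep(c("50-54", "55-59", "50-54"), 2),
    red_meat = c(26, 60, 0, 11, 30, 26),
    processed_meat = c(47, 78, 5, 23, 42, 0),
    weight = 1
  )
}

# Brute-force RR-shift PIF with explicit loops (independent oracle).
pif_oracle <- function(rr0, rr1, w) {
  num <- 0
  den <- 0
  for (i in seq_along(rr0)) {
    num <- num + w[i] * rr1[i]
    den <- den + w[i] * rr0[i]
  }
  1 - num / den
}

# Small single-stratum survey drawn from a lognormal fit.
lognormal_records <- function(n, mu, sigma, seed = 99) {
  set.seed(seed)
  tibble::tibble(
    id = paste0("x", seq_len(n)), sex = "male", age_group = "50-54",
    red_meat = 0, processed_meat = stats::rlnorm(n, mu, sigma), weight = 1
  )
}
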