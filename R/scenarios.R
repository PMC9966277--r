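#' Grams per day in one weekly serving of meat
#'
#' One serving of 75 g per week averaged over the week, i.e. approximately
#' 10.7 g per day. Used as the unit of the serving-reduction scenarios.
#'
#' @return A single number (grams/day).
#' @export
serving_g_day <- function() 10.7

#' Define an intervention scenario
#'
#' A scenario transforms the intake of one or more risk factors, either by a
#' fixed daily reduction in grams (floored at zero) or by complete
#' elimination.
#'
#' @param name Scenario label; appears verbatim in output tables.
#' @param targets Character vector of risk-factor names the scenario acts on.
#' @param mode `"reduce_grams"` or `"eliminate"`.
#' @param delta_g_day Daily reduction in grams (> 0); required when
#'   `mode = "reduce_grams"`, ignored otherwise.
#' @return An object of class `scenario`.
#' @examples
#' scenario("processed_minus_1", "processed_meat", "reduce_grams",
#'          delta_g_day = serving_g_day())
#' @export
scenario <- function(name, targets, mode = c("reduce_grams", "eliminate"),
                     delta_g_day = NULL) {
  mode <- match.arg(mode)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a single non-empty string", call. = FALSE)
  }
  if (!is.character(targets) || length(targets) < 1L) {
    stop("`targets` must name at least one risk factor", call. = FALSE)
  }
  if (mode == "reduce_grams") {
    if (is.null(delta_g_day) || !is.numeric(delta_g_day) ||
        length(delta_g_day) != 1L || !is.finite(delta_g_day) ||
        delta_g_day <= 0) {
      stop("`delta_g_day` must be a single positive number for reduce_grams",
           call. = FALSE)
    }
    delta_g_day <- as.numeric(delta_g_day)
  } else {
    delta_g_day <- NULL
  }
  structure(list(name = name, targets = targets, mode = mode,
                 delta_g_day = delta_g_day),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  act <- if (x$mode == "eliminate") "eliminate"
         else sprintf("reduce by %.4g g/day", x$delta_g_day)
  cat(sprintf("<scenario> %s: %s [%s]\n", x$name, act,
              paste(x$targets, collapse = ", ")))
  invisible(x)
}

#' Default intervention scenarios
#'
#' For each meat type separately: reduction by one serving per day, by two
#' servings per day, and elimination (six scenarios). One serving is
#' [serving_g_day()] grams per day.
#'
#' @return Named list of [scenario()] objects, in dominance order
#'   (1 serving, 2 servings, elimination) per factor.
#' @export
default_scenarios <- function() {
  s <- serving_g_day()
  list(
    red_minus_1 = scenario("red_minus_1", "red_meat", "reduce_grams", s),
    red_minus_2 = scenario("red_minus_2", "red_meat", "reduce_grams", 2 * s),
    red_elimination = scenario("red_elimination", "red_meat", "eliminate"),
    processed_minus_1 = scenario("processed_minus_1", "processed_meat",
                                 "reduce_grams", s),
    processed_minus_2 = scenario("processed_minus_2", "processed_meat",
                                 "reduce_grams", 2 * s),
    processed_elimination = scenario("processed_elimination", "processed_meat",
                                     "eliminate")
  )
}

#' Apply a scenario to exposure records
#'
#' Targeted intake columns become 0 (`eliminate`) or
#' `max(0, intake - delta_g_day)` (`reduce_grams`); all other columns are
#' untouched.
#'
#' @param records Data frame of exposure records with one intake column per
#'   risk factor.
#' @param scen A [scenario()].
#' @return The transformed records, same shape and row order.
#' @export
apply_scenario <- function(records, scen) {
  stopifnot(is.data.frame(records), inherits(scen, "scenario"))
  missing <- setdiff(scen$targets, names(records))
  if (length(missing)) {
    stop(sprintf("scenario '%s' targets unknown factor(s): %s",
                 scen$name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (tgt in scen$targets) {
    records[[tgt]] <- switch(
      scen$mode,
      eliminate = rep(0, nrow(records)),
      reduce_grams = pmax(0, records[[tgt]] - scen$delta_g_day)
    )
  }
  records
}

#' Define the latency/lag temporal model
#'
#' After an intervention starts, cancer risk stays at its baseline level for
#' `latency_years` (LAT), then moves gradually to its counterfactual level
#' over the following `lag_years` (LAG).
#'
#' @param start_year Calendar year the intervention begins.
#' @param latency_years LAT, years with no risk change (>= 0). Default 1.
#' @param lag_years LAG, years of gradual risk transition (> 0). Default 9.
#' @param horizon Integer vector of simulation years (inclusive). Default
#'   2020:2050.
#' @return An object of class `temporal_model`.
#' @export
temporal_model <- function(start_year = 2020, latency_years = 1,
                           lag_years = 9, horizon = 2020:2050) {
  stopifnot(is.numeric(start_year), length(start_year) == 1L)
  if (!is.numeric(latency_years) || latency_years < 0) {
    stop("`latency_years` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(lag_years) || lag_years <= 0) {
    stop("`lag_years` must be > 0", call. = FALSE)
  }
  horizon <- sort(unique(as.integer(horizon)))
  if (!length(horizon)) stop("`horizon` must be non-empty", call. = FALSE)
  structure(list(start_year = as.integer(start_year),
                 latency_years = as.numeric(latency_years),
                 lag_years = as.numeric(lag_years),
                 horizon = horizon),
            class = "temporal_model")
}

#' @export
print.temporal_model <- function(x, ...) {
  cat(sprintf("<temporal_model> start %d, LAT %g y, LAG %g y, horizon %d-%d\n",
              x$start_year, x$latency_years, x$lag_years,
              min(x$horizon), max(x$horizon)))
  invisible(x)
}

#' Risk-transition ramp factor for a calendar year
#'
#' `clamp((year - start_year - latency_years) / lag_years, 0, 1)`: the
#' completed fraction of the risk transition at the start of `year`. Zero
#' through the latency period, 1 once latency + lag have elapsed,
#' non-decreasing in between.
#'
#' @param year Integer calendar year(s).
#' @param temporal A [temporal_model()].
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' tm <- temporal_model(2020, latency_years = 1, lag_years = 9)
#' ramp_factor(c(2020, 2026, 2030), tm)  # 0, 5/9, 1
#' @export
ramp_factor <- function(year, temporal) {
  stopifnot(inherits(temporal, "temporal_model"))
  f <- (year - temporal$start_year - temporal$latency_years) /
    temporal$lag_years
  pmin(1, pmax(0, f))
}

#' Yearly potential impact fraction trajectory for one stratum
#'
#' For each year of the horizon, each individual's time-dependent RR is
#' interpolated between the baseline RR and the post-scenario RR by the
#' latency/lag ramp, and the stratum PIF is computed with the RR-shift
#' method. The trajectory is non-decreasing over years and constant once the
#' ramp reaches 1.
#'
#' With `phase_in_years > 0`, the intake change itself is additionally phased
#' in linearly over that many years from `start_year` (the change is complete
#' at `start_year + phase_in_years - 1`); each year's ramp then interpolates
#' towards that year's phased intake target rather than the final one.
#'
#' @param records Exposure records of a single stratum (already filtered to
#'   one sex and age group); must be non-empty. An optional `weight` column
#'   is used as sampling weights.
#' @param scen A [scenario()].
#' @param factors List of [risk_factor()] objects defining the combined RR.
#' @param temporal A [temporal_model()].
#' @param phase_in_years Optional linear exposure phase-in duration in years
#'   (0 = the intake change is immediate and only LAT/LAG delays the risk
#'   response; the default).
#' @return A tibble with columns `year`, `ramp`, `pif`.
#' @export
yearly_pif_trajectory <- function(records, scen, factors, temporal,
                                  phase_in_years = 0) {
  stopifnot(is.data.frame(records), inherits(temporal, "temporal_model"))
  if (nrow(records) == 0L) {
    stop("empty stratum: PIF is undefined (report as missing, not zero)",
         call. = FALSE)
  }
  w <- if ("weight" %in% names(records)) records$weight else rep(1, nrow(records))
  rr_base <- combined_rr(records, factors)
  modified <- apply_scenario(records, scen)
  years <- temporal$horizon
  ramps <- ramp_factor(years, temporal)
  pifs <- numeric(length(years))
  if (phase_in_years > 0) {
    for (k in seq_along(years)) {
      p <- min(1, max(0, (years[k] - temporal$start_year + 1) / phase_in_years))
      phased <- records
      for (tgt in scen$targets) {
        phased[[tgt]] <- (1 - p) * records[[tgt]] + p * modified[[tgt]]
      }
      rr_tgt <- combined_rr(phased, factors)
      rr_y <- time_dependent_rr(rr_base, rr_tgt, ramps[k])
      pifs[k] <- pif_rr_shift(rr_base, rr_y, w)
    }
  } else {
    rr_tgt <- combined_rr(modified, factors)
    log_base <- log(rr_base)
    log_tgt <- log(rr_tgt)
    for (k in seq_along(years)) {
      rr_y <- exp((1 - ramps[k]) * log_base + ramps[k] * log_tgt)
      pifs[k] <- pif_rr_shift(rr_base, rr_y, w)
    }
  }
  tibble::tibble(year = years, ramp = ramps, pif = pifs)
}
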