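#' Define a dose-response risk factor
#'
#' A risk factor is parameterised by the relative risk (RR) attached to one
#' reference unit of daily intake, e.g. an RR of 1.16 per 50 g/day of
#' processed meat or 1.12 per 100 g/day of red meat. Under the log-linear
#' dose-response model used throughout the package, risk multiplies by
#' `rr_per_unit` for every additional `reference_grams` grams per day.
#'
#' @param name Factor label, e.g. `"processed_meat"`. Used to look up intake
#'   columns in exposure tables, so it must be a valid column name.
#' @param rr_per_unit Relative risk per one reference unit of daily intake
#'   (dimensionless, > 0).
#' @param reference_grams Grams per day constituting one reference unit (> 0).
#' @return An object of class `risk_factor`.
#' @examples
#' processed <- risk_factor("processed_meat", rr_per_unit = 1.16,
#'                          reference_grams = 50)
#' individual_rr(50, processed)
#' @export
risk_factor <- function(name, rr_per_unit, reference_grams) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a single non-empty string", call. = FALSE)
  }
  if (!is.numeric(rr_per_unit) || length(rr_per_unit) != 1L ||
      !is.finite(rr_per_unit) || rr_per_unit <= 0) {
    stop("`rr_per_unit` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(reference_grams) || length(reference_grams) != 1L ||
      !is.finite(reference_grams) || reference_grams <= 0) {
    stop("`reference_grams` must be a single positive number", call. = FALSE)
  }
  structure(
    list(name = name, rr_per_unit = as.numeric(rr_per_unit),
         reference_grams = as.numeric(reference_grams)),
    class = "risk_factor"
  )
}

#' @export
print.risk_factor <- function(x, ...) {
  cat(sprintf("<risk_factor> %s: RR %.4g per %g g/day\n",
              x$name, x$rr_per_unit, x$reference_grams))
  invisible(x)
}

#' Default meat risk factors
#'
#' The WCRF/IARC continuous dose-response estimates for colorectal cancer:
#' RR 1.12 per 100 g/day of red meat and RR 1.16 per 50 g/day of processed
#' meat.
#'
#' @return A named list of two [risk_factor()] objects,
#'   `red_meat` and `processed_meat`.
#' @export
default_risk_factors <- function() {
  list(
    red_meat = risk_factor("red_meat", rr_per_unit = 1.12,
                           reference_grams = 100),
    processed_meat = risk_factor("processed_meat", rr_per_unit = 1.16,
                                 reference_grams = 50)
  )
}

#' Individual relative risk under the log-linear dose-response
#'
#' Computes `RR_i = exp(intake * log(rr_per_unit) / reference_grams)`, the
#' relative risk of an individual consuming `intake_g_day` grams per day
#' compared to zero intake. The model is multiplicative in intake increments:
#' `individual_rr(a + b) == individual_rr(a) * individual_rr(b)`.
#'
#' @param intake_g_day Numeric vector of daily intakes in grams (>= 0).
#' @param factor A [risk_factor()].
#' @return Numeric vector of relative risks; exactly 1 at zero intake.
#' @examples
#' # half a 100 g reference unit at RR 1.16:
#' individual_rr(50, risk_factor("x", 1.16, 100))  # 1.077, prints as 1.08
#' @export
individual_rr <- function(intake_g_day, factor) {
  stopifnot(inherits(factor, "risk_factor"))
  if (!is.numeric(intake_g_day)) {
    stop("`intake_g_day` must be numeric", call. = FALSE)
  }
  bad <- which(!is.finite(intake_g_day) | intake_g_day < 0)
  if (length(bad)) {
    stop(sprintf("negative or non-finite %s intake for record(s) %s",
                 factor$name,
                 paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  }
  exp(intake_g_day * log(factor$rr_per_unit) / factor$reference_grams)
}

#' Combined relative risk across several risk factors
#'
#' Multiplies the per-factor log-linear relative risks of each individual.
#' Independent log-linear terms combine multiplicatively, which is the
#' convention adopted here for joint red + processed meat risk.
#'
#' @param records A data frame of exposure records with one intake column
#'   (grams/day) per risk factor, named after the factor.
#' @param factors A list of [risk_factor()] objects (or a single one).
#' @return Numeric vector, one combined RR per record, vs zero intake of all
#'   requested factors.
#' @export
combined_rr <- function(records, factors) {
  if (inherits(factors, "risk_factor")) factors <- list(factors)
  stopifnot(is.data.frame(records), length(factors) >= 1L)
  rr <- rep(1.0, nrow(records))
  for (f in factors) {
    stopifnot(inherits(f, "risk_factor"))
    if (!f$name %in% names(records)) {
      stop(sprintf("exposure records have no intake column for factor '%s'",
                   f$name), call. = FALSE)
    }
    rr <- rr * individual_rr(records[[f$name]], f)
  }
  rr
}

#' Potential impact fraction by the RR-shift method
#'
#' `PIF = 1 - sum(w * rr_modified) / sum(w * rr_baseline)`, where baseline and
#' modified relative risks are paired individual by individual. With all
#' modified RRs equal to 1 this reduces to the population attributable
#' fraction (PAF) `1 - sum(w) / sum(w * rr_baseline)`.
#'
#' @param baseline_rr Numeric vector of individual RRs under current exposure.
#' @param modified_rr Numeric vector of individual RRs under the
#'   counterfactual exposure, same length and order as `baseline_rr`.
#' @param weights Non-negative sampling weights, recycled scalar or one per
#'   individual; default 1.
#' @return A single fraction, <= 1; 0 when the two RR vectors are identical.
#' @examples
#' pif_rr_shift(c(1, 2), c(1, 1))  # 1 - 2/3
#' @export
pif_rr_shift <- function(baseline_rr, modified_rr, weights = 1) {
  n <- length(baseline_rr)
  if (n == 0L) stop("empty RR input: PIF is undefined", call. = FALSE)
  if (length(modified_rr) != n) {
    stop(sprintf("baseline (%d) and modified (%d) RR vectors differ in length",
                 n, length(modified_rr)), call. = FALSE)
  }
  if (length(weights) == 1L) weights <- rep(weights, n)
  if (length(weights) != n) {
    stop("`weights` must be scalar or match the number of individuals",
         call. = FALSE)
  }
  if (any(!is.finite(weights) | weights < 0)) {
    stop("`weights` must be finite and non-negative", call. = FALSE)
  }
  denom <- sum(weights * baseline_rr)
  if (denom <= 0) {
    stop("all weights are zero: PIF is undefined", call. = FALSE)
  }
  1 - sum(weights * modified_rr) / denom
}

#' Time-dependent relative risk during risk reversal
#'
#' After an exposure change, excess risk is assumed to decay towards its new
#' level along a ramp: `exp((1 - ramp) * log(rr_baseline) + ramp *
#' log(rr_target))`. Interpolation on the log-RR scale is equivalent, under
#' the log-linear dose-response, to linearly shrinking the effective intake
#' from its baseline to its counterfactual level.
#'
#' @param rr_baseline Relative risk before the intervention takes effect (> 0).
#' @param rr_target Relative risk once the change is complete (> 0).
#' @param ramp Completed fraction of the risk transition, in \[0, 1\]
#'   (see [ramp_factor()]).
#' @return Interpolated relative risk(s); baseline at `ramp = 0`, target at
#'   `ramp = 1`.
#' @export
time_dependent_rr <- function(rr_baseline, rr_target, ramp) {
  if (any(!is.finite(ramp) | ramp < 0 | ramp > 1)) {
    stop("`ramp` must lie in [0, 1]", call. = FALSE)
  }
  if (any(rr_baseline <= 0) || any(rr_target <= 0)) {
    stop("relative risks must be positive", call. = FALSE)
  }
  exp((1 - ramp) * log(rr_baseline) + ramp * log(rr_target))
}
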