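#' @importFrom dplyr .data
NULL

valid_sexes <- c("male", "female")

#' Read an exposure survey from CSV
#'
#' Expects a header row with columns `id`, `sex`, `age_group`,
#' `red_meat_g_day`, `processed_meat_g_day`, and optionally `weight`
#' (defaulting to 1). Validation errors carry the offending data row
#' numbers.
#'
#' @param path Path to a comma-separated, UTF-8, `.`-decimal CSV file.
#' @return A tibble of exposure records with intake columns `red_meat` and
#'   `processed_meat` in grams/day.
#' @export
read_survey_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  required <- c("id", "sex", "age_group", "red_meat_g_day",
                "processed_meat_g_day")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!"weight" %in% names(df)) df$weight <- 1
  complain <- function(rows, what) {
    if (length(rows)) {
      stop(sprintf("%s: %s on row(s) %s", path, what,
                   paste(utils::head(rows, 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  complain(which(!df$sex %in% valid_sexes), "unknown sex label")
  complain(which(!df$age_group %in% c(age_bands(), "all")),
           "unknown age_group label")
  for (col in c("red_meat_g_day", "processed_meat_g_day")) {
    complain(which(!is.finite(df[[col]]) | df[[col]] < 0),
             sprintf("negative or non-numeric %s", col))
  }
  complain(which(!is.finite(df$weight) | df$weight < 0), "invalid weight")
  tibble::tibble(id = as.character(df$id), sex = df$sex,
                 age_group = df$age_group,
                 red_meat = as.numeric(df$red_meat_g_day),
                 processed_meat = as.numeric(df$processed_meat_g_day),
                 weight = as.numeric(df$weight))
}

#' Write an exposure survey to CSV
#'
#' Inverse of [read_survey_csv()]; a write-then-read round trip reproduces
#' the records.
#'
#' @param records Exposure record tibble with `red_meat` and
#'   `processed_meat` intake columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(records, path) {
  out <- data.frame(id = records$id, sex = records$sex,
                    age_group = records$age_group,
                    red_meat_g_day = records$red_meat,
                    processed_meat_g_day = records$processed_meat,
                    weight = if ("weight" %in% names(records))
                      records$weight else 1)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an incidence table from CSV
#'
#' Columns: `sex`, `age_group`, `rate_per_100k`.
#'
#' @param path CSV file path.
#' @return A tibble `sex`, `age_group`, `rate`.
#' @export
read_incidence_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  required <- c("sex", "age_group", "rate_per_100k")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!is.finite(df$rate_per_100k) | df$rate_per_100k < 0)
  if (length(bad)) {
    stop(sprintf("%s: negative or non-numeric rate on row(s) %s", path,
                 paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  }
  tibble::tibble(sex = df$sex, age_group = df$age_group,
                 rate = as.numeric(df$rate_per_100k))
}

#' Read a population projection from CSV
#'
#' Columns: `year`, `sex`, `age_group`, `count`.
#'
#' @param path CSV file path.
#' @return A tibble `year`, `sex`, `age_group`, `count`.
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  required <- c("year", "sex", "age_group", "count")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!is.finite(df$count) | df$count < 0)
  if (length(bad)) {
    stop(sprintf("%s: negative or non-numeric count on row(s) %s", path,
                 paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  }
  tibble::tibble(year = as.integer(df$year), sex = df$sex,
                 age_group = df$age_group, count = as.numeric(df$count))
}

#' Default run configuration
#'
#' The main-analysis configuration: WCRF/IARC risk factors, the six
#' serving-reduction and elimination scenarios, interventions starting 2020
#' with a 1-year latency and lag variants of 9 (main), 5, and 15 years over
#' the 2020-2050 horizon, and synthetic inputs (survey calibrated to the
#' published intake margins, exponential-in-age incidence, cohort-drift
#' population).
#'
#' @param seed Integer seed driving all synthetic generation.
#' @return A `run_config` list accepted by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    risk_factors = list(
      list(name = "red_meat", rr_per_unit = 1.12, reference_grams = 100),
      list(name = "processed_meat", rr_per_unit = 1.16, reference_grams = 50)
    ),
    scenarios = lapply(unname(default_scenarios()), function(s) {
      list(name = s$name, targets = s$targets, mode = s$mode,
           delta_g_day = s$delta_g_day)
    }),
    temporal = list(start_year = 2020, latency_years = 1,
                    lag_years = c(9, 5, 15)),
    horizon = c(2020, 2050),
    phase_in_years = 0,
    survey = list(synthetic = list(n_per_stratum = 400,
                                   seed = as.integer(seed),
                                   rank_correlation = 0.3)),
    incidence = list(synthetic = list(base_rate = 39,
                                      reference_group = "50-54",
                                      doubling_years = 10,
                                      male_female_ratio = 1.3)),
    population = list(synthetic = list(kind = "cohort_drift",
                                       entry = 375000))
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Parses and validates the structured run configuration consumed by
#' [run_pipeline()]. See [default_run_config()] for the schema; each of
#' `survey`, `incidence`, and `population` takes either a `file:` path or a
#' `synthetic:` parameter block, and a seed is mandatory whenever a
#' synthetic survey block is used.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  fail <- function(msg) stop(sprintf("invalid config: %s", msg),
                             call. = FALSE)
  if (!length(cfg$risk_factors)) fail("at least one risk factor required")
  for (f in cfg$risk_factors) {
    risk_factor(f$name, f$rr_per_unit, f$reference_grams)  # validates
  }
  if (!length(cfg$scenarios)) fail("at least one scenario required")
  for (s in cfg$scenarios) {
    scenario(s$name, unlist(s$targets), s$mode,
             delta_g_day = s$delta_g_day)
  }
  tm <- cfg$temporal
  if (is.null(tm$start_year)) fail("temporal$start_year required")
  if (!length(tm$lag_years) || any(unlist(tm$lag_years) <= 0)) {
    fail("temporal$lag_years must list positive lag durations")
  }
  if (length(cfg$horizon) != 2L || cfg$horizon[1] > cfg$horizon[2]) {
    fail("horizon must be c(first_year, last_year)")
  }
  if (!is.null(cfg$survey$synthetic) &&
      is.null(cfg$survey$synthetic$seed)) {
    fail("a seed is required when the survey is generated synthetically")
  }
  if (is.null(cfg$survey$synthetic) && is.null(cfg$survey$file)) {
    fail("survey needs either a `file` path or a `synthetic` block")
  }
  structure(cfg, class = "run_config")
}
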