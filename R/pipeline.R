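stage_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

# Resolve the survey input: synthetic generation or CSV file.
resolve_survey <- function(cfg, verbose) {
  if (!is.null(cfg$survey$file)) {
    stage_msg(verbose, "survey: reading %s", cfg$survey$file)
    return(read_survey_csv(cfg$survey$file))
  }
  syn <- cfg$survey$synthetic
  fits <- default_intake_fits(
    zero_mass = if (is.null(syn$zero_mass)) 0 else syn$zero_mass)
  rc <- if (is.null(syn$rank_correlation)) 0.3 else syn$rank_correlation
  generate_survey(fits, n_per_stratum = syn$n_per_stratum, seed = syn$seed,
                  rank_correlation = rc)
}

resolve_incidence <- function(cfg) {
  if (!is.null(cfg$incidence$file)) {
    return(read_incidence_csv(cfg$incidence$file))
  }
  syn <- cfg$incidence$synthetic
  if (is.null(syn)) syn <- list()
  args <- syn[intersect(names(syn), names(formals(generate_incidence)))]
  do.call(generate_incidence, args)
}

resolve_population <- function(cfg, years) {
  if (!is.null(cfg$population$file)) {
    return(read_population_csv(cfg$population$file))
  }
  syn <- cfg$population$synthetic
  if (is.null(syn)) syn <- list(kind = "cohort_drift")
  kind <- if (is.null(syn$kind)) "cohort_drift" else syn$kind
  if (kind == "constant") {
    constant_population(years = years)
  } else {
    entry <- if (is.null(syn$entry)) 375000 else syn$entry
    generate_population(years = years, entry = entry)
  }
}

#' Run the full macro-simulation pipeline
#'
#' Executes every stage on a validated configuration: obtain the exposure
#' survey, incidence table, and population projection (from files or the
#' synthetic generators); compute stratum-level PIF trajectories for every
#' scenario and lag variant; multiply them with expected case numbers; and
#' summarise. Strata with expected cases but no survey records (the under-18
#' band, by construction) enter with an explicit PIF of 0, since no exposure
#' is modelled there. Given the same configuration and seeds, the output —
#' including any files written — is identical across runs.
#'
#' @param config A `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @param output_dir Optional directory; when given, writes
#'   `projection.csv`, `summary.csv`, `summary.txt`, `annual_series.csv`,
#'   `survey.csv`, and `manifest.json` there (creating it if needed). On
#'   any failure no partial outputs are left behind.
#' @param verbose Log stage progress and record counts to stderr.
#' @return A list with elements `survey`, `incidence`, `population`,
#'   `expected`, `projection` (the full `projection_table`), `summary`,
#'   `series`, and `manifest`.
#' @export
run_pipeline <- function(config, output_dir = NULL, verbose = TRUE) {
  cfg <- validate_run_config(unclass(config))
  years <- seq.int(cfg$horizon[1], cfg$horizon[2])

  stage_msg(verbose, "stage survey: resolving exposure records")
  survey <- resolve_survey(cfg, verbose)
  stage_msg(verbose, "stage survey: %d records, %d strata", nrow(survey),
            nrow(unique(survey[, c("sex", "age_group")])))

  stage_msg(verbose, "stage rates: incidence and population")
  incidence <- resolve_incidence(cfg)
  population <- resolve_population(cfg, years)
  expected <- expected_cases(incidence, population)

  factors <- lapply(cfg$risk_factors, function(f) {
    risk_factor(f$name, f$rr_per_unit, f$reference_grams)
  })
  scenarios <- lapply(cfg$scenarios, function(s) {
    scenario(s$name, unlist(s$targets), s$mode, delta_g_day = s$delta_g_day)
  })
  phase_in <- if (is.null(cfg$phase_in_years)) 0 else cfg$phase_in_years

  stage_msg(verbose, "stage pif: %d scenarios x %d lag variants",
            length(scenarios), length(unlist(cfg$temporal$lag_years)))
  strata <- unique(expected[, c("sex", "age_group")])
  lat <- if (is.null(cfg$temporal$latency_years)) 1
         else cfg$temporal$latency_years
  pif_rows <- list()
  for (lag in unlist(cfg$temporal$lag_years)) {
    tm <- temporal_model(start_year = cfg$temporal$start_year,
                         latency_years = lat,
                         lag_years = lag, horizon = years)
    for (scen in scenarios) {
      for (i in seq_len(nrow(strata))) {
        sx <- strata$sex[i]
        ag <- strata$age_group[i]
        rec <- survey[survey$sex == sx & survey$age_group == ag, ]
        if (nrow(rec) == 0L) {
          # no exposure data for this stratum: no modelled impact
          traj <- tibble::tibble(year = years, pif = 0)
        } else {
          traj <- yearly_pif_trajectory(rec, scen, factors, tm,
                                        phase_in_years = phase_in)
        }
        pif_rows[[length(pif_rows) + 1L]] <- tibble::tibble(
          year = traj$year, sex = sx, age_group = ag,
          scenario = scen$name, lag_years = lag, pif = traj$pif)
      }
    }
  }
  pifs <- dplyr::bind_rows(pif_rows)

  stage_msg(verbose, "stage projection: combining cases and PIFs")
  projection <- prevented_cases(expected, pifs)
  summary <- summarize_projection(projection)
  series <- annual_series(projection)

  manifest <- list(
    package = "pifsim",
    package_version = as.character(utils::packageVersion("pifsim")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(cfg)
  )

  result <- list(survey = survey, incidence = incidence,
                 population = population, expected = expected,
                 projection = projection, summary = summary,
                 series = series, manifest = manifest)

  if (!is.null(output_dir)) {
    stage_msg(verbose, "stage output: writing to %s", output_dir)
    write_pipeline_outputs(result, output_dir)
  }
  result
}

write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop(sprintf("stage output failed (%s); partial files removed",
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    emit <- function(obj, name) {
      p <- file.path(output_dir, name)
      utils::write.csv(obj, p, row.names = FALSE, fileEncoding = "UTF-8")
      written <<- c(written, p)
    }
    p <- file.path(output_dir, "survey.csv")
    write_survey_csv(result$survey, p)
    written <- c(written, p)
    emit(result$projection, "projection.csv")
    emit(result$summary, "summary.csv")
    emit(result$series, "annual_series.csv")
    p <- file.path(output_dir, "summary.txt")
    writeLines(format_summary_table(result$summary), p)
    written <- c(written, p)
    p <- file.path(output_dir, "manifest.json")
    jsonlite::write_json(result$manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, p)
  }, error = on_fail)
  invisible(output_dir)
}

#' Write a small deterministic fixture data set
#'
#' Emits a miniature synthetic survey, incidence table, and population
#' projection as CSV files — a self-contained input set for examples and
#' round-trip tests.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed. Default 42.
#' @return The directory path, invisibly.
#' @export
write_fixtures <- function(dir, seed = 42L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  survey <- generate_survey(default_intake_fits(), n_per_stratum = 5,
                            seed = seed)
  write_survey_csv(survey, file.path(dir, "survey.csv"))
  inc <- generate_incidence()
  utils::write.csv(
    data.frame(sex = inc$sex, age_group = inc$age_group,
               rate_per_100k = inc$rate),
    file.path(dir, "incidence.csv"), row.names = FALSE)
  pop <- constant_population(years = 2020:2024)
  utils::write.csv(pop, file.path(dir, "population.csv"), row.names = FALSE)
  invisible(dir)
}
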