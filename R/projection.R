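#' Expected case numbers without intervention
#'
#' Multiplies constant age- and sex-specific incidence rates with projected
#' population counts: `cases = rate * count / 100000` for every year and
#' stratum.
#'
#' @param incidence Tibble `sex`, `age_group`, `rate` (per 100,000
#'   person-years), e.g. from [generate_incidence()] or
#'   [read_incidence_csv()].
#' @param population Tibble `year`, `sex`, `age_group`, `count`, e.g. from
#'   [generate_population()] or [constant_population()].
#' @return A tibble `year`, `sex`, `age_group`, `expected_cases`.
#' @export
expected_cases <- function(incidence, population) {
  stopifnot(all(c("sex", "age_group", "rate") %in% names(incidence)),
            all(c("year", "sex", "age_group", "count") %in% names(population)))
  if (any(incidence$rate < 0)) stop("rates must be >= 0", call. = FALSE)
  key_i <- unique(paste(incidence$sex, incidence$age_group, sep = "|"))
  key_p <- unique(paste(population$sex, population$age_group, sep = "|"))
  only_p <- setdiff(key_p, key_i)
  only_i <- setdiff(key_i, key_p)
  if (length(only_p) || length(only_i)) {
    stop(sprintf(
      "incidence and population strata do not align; missing from incidence: %s; missing from population: %s",
      paste(utils::head(only_p, 5L), collapse = ", "),
      paste(utils::head(only_i, 5L), collapse = ", ")), call. = FALSE)
  }
  out <- dplyr::inner_join(population, incidence, by = c("sex", "age_group"))
  out$expected_cases <- out$rate * out$count / 1e5
  dplyr::arrange(out[, c("year", "sex", "age_group", "expected_cases")],
                 .data$year, .data$sex, .data$age_group)
}

#' Combine expected cases with PIF trajectories into a projection table
#'
#' Each cell's prevented cases are `expected_cases * pif`, with a running
#' cumulative sum over years within every scenario, lag variant, sex, and
#' age group. A PIF that is missing for a stratum-year with non-zero
#' expected cases is an error, so that absent exposure data cannot silently
#' count as a zero impact — strata known to carry no modelled exposure must
#' be given an explicit PIF of 0 upstream.
#'
#' @param expected Tibble from [expected_cases()].
#' @param pifs Tibble `year`, `sex`, `age_group`, `scenario`, `lag_years`,
#'   `pif`.
#' @return A `projection_table` tibble: `year`, `sex`, `age_group`,
#'   `scenario`, `lag_years`, `expected_cases`, `pif`, `prevented`,
#'   `cumulative_prevented`.
#' @export
prevented_cases <- function(expected, pifs) {
  stopifnot(all(c("year", "sex", "age_group", "expected_cases") %in%
                  names(expected)),
            all(c("year", "sex", "age_group", "scenario", "lag_years",
                  "pif") %in% names(pifs)))
  key <- function(d) paste(d$year, d$sex, d$age_group, sep = "|")
  need <- unique(key(expected[expected$expected_cases > 0, ]))
  have <- unique(key(pifs))
  gap <- setdiff(need, have)
  if (length(gap)) {
    stop(sprintf(
      "PIF missing for %d stratum-year(s) with non-zero expected cases, e.g. %s",
      length(gap), paste(utils::head(gap, 5L), collapse = "; ")),
      call. = FALSE)
  }
  out <- dplyr::inner_join(pifs, expected, by = c("year", "sex", "age_group"))
  out$prevented <- out$expected_cases * out$pif
  out <- dplyr::arrange(out, .data$scenario, .data$lag_years, .data$sex,
                        .data$age_group, .data$year)
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$scenario, .data$lag_years, .data$sex,
                    .data$age_group),
    cumulative_prevented = cumsum(.data$prevented))
  out <- dplyr::ungroup(out)
  out <- out[, c("year", "sex", "age_group", "scenario", "lag_years",
                 "expected_cases", "pif", "prevented",
                 "cumulative_prevented")]
  class(out) <- c("projection_table", class(out))
  out
}

#' Summarise a projection as a per-sex scenario report
#'
#' Totals prevented cases over the whole horizon per sex, scenario, and lag
#' variant, together with the sex-specific expected total and the prevented
#' percentage `100 * prevented / expected`, computed from unrounded totals
#' and rounded to one decimal. Rows with `sex = "both"` aggregate the two
#' sexes for headline figures.
#'
#' @param projection A `projection_table` from [prevented_cases()].
#' @return A tibble `lag_years`, `sex`, `scenario`, `expected_cases`,
#'   `prevented`, `pct_prevented`.
#' @export
summarize_projection <- function(projection) {
  stopifnot(is.data.frame(projection))
  exp_by_sex <- dplyr::distinct(
    projection, .data$year, .data$sex, .data$age_group,
    .data$expected_cases)
  exp_tot <- dplyr::summarise(dplyr::group_by(exp_by_sex, .data$sex),
                              expected_cases = sum(.data$expected_cases),
                              .groups = "drop")
  prev <- dplyr::summarise(
    dplyr::group_by(projection, .data$lag_years, .data$scenario, .data$sex),
    prevented = sum(.data$prevented), .groups = "drop")
  per_sex <- dplyr::left_join(prev, exp_tot, by = "sex")
  both <- dplyr::summarise(
    dplyr::group_by(per_sex, .data$lag_years, .data$scenario),
    sex = "both", prevented = sum(.data$prevented),
    expected_cases = sum(.data$expected_cases), .groups = "drop")
  out <- dplyr::bind_rows(per_sex, both)
  out$pct_prevented <- round(100 * out$prevented / out$expected_cases, 1)
  dplyr::arrange(
    out[, c("lag_years", "sex", "scenario", "expected_cases", "prevented",
            "pct_prevented")],
    .data$lag_years, .data$sex, .data$scenario)
}

#' Prevented-case percentage from report totals
#'
#' The report arithmetic in one place: `100 * prevented / expected`, rounded
#' to one decimal, as printed in scenario summary tables.
#'
#' @param prevented Total prevented cases.
#' @param expected Total expected cases (> 0).
#' @return Percentage rounded to one decimal.
#' @examples
#' prevented_pct(145291, 1208329)  # 12.0
#' @export
prevented_pct <- function(prevented, expected) {
  if (any(expected <= 0)) stop("`expected` must be positive", call. = FALSE)
  round(100 * prevented / expected, 1)
}

#' Annual and cumulative prevented-case series (sexes combined)
#'
#' Aggregates a projection table to one row per scenario, lag variant, and
#' year — the series behind "prevented cases per year" and "cumulative
#' prevented cases" figures.
#'
#' @param projection A `projection_table` from [prevented_cases()].
#' @return A tibble `scenario`, `lag_years`, `year`, `prevented`,
#'   `cumulative_prevented`.
#' @export
annual_series <- function(projection) {
  out <- dplyr::summarise(
    dplyr::group_by(projection, .data$scenario, .data$lag_years, .data$year),
    prevented = sum(.data$prevented), .groups = "drop")
  out <- dplyr::arrange(out, .data$scenario, .data$lag_years, .data$year)
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$scenario, .data$lag_years),
    cumulative_prevented = cumsum(.data$prevented))
  dplyr::ungroup(out)
}

#' Format a summary as a plain-text scenario table
#'
#' Renders the output of [summarize_projection()] as a fixed-width text
#' table, one block per lag variant and sex, with a `#` (total prevented,
#' rounded to whole cases) and `%` column per scenario.
#'
#' @param summary Tibble from [summarize_projection()].
#' @return Character vector of lines, invisibly printed with `cat()` when
#'   autoprinted.
#' @export
format_summary_table <- function(summary) {
  lines <- character(0)
  for (lag in unique(summary$lag_years)) {
    lines <- c(lines, sprintf("Lag time: %g years", lag))
    block <- summary[summary$lag_years == lag, ]
    for (sx in unique(block$sex)) {
      rows <- block[block$sex == sx, ]
      lines <- c(lines, sprintf("  %s (expected cases: %s)", sx,
                                format(round(rows$expected_cases[1L]),
                                       big.mark = ",", scientific = FALSE)))
      lines <- c(lines, sprintf("    %-28s %12s %8s", "scenario", "#", "%"))
      for (j in seq_len(nrow(rows))) {
        lines <- c(lines, sprintf(
          "    %-28s %12s %8.1f", rows$scenario[j],
          format(round(rows$prevented[j]), big.mark = ",",
                 scientific = FALSE),
          rows$pct_prevented[j]))
      }
    }
  }
  lines
}
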