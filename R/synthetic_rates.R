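# Midpoint in years of an age band label ("a-b" or "a+").
band_midpoint <- function(band) {
  vapply(band, function(b) {
    if (grepl("\\+$", b)) {
      as.numeric(sub("\\+$", "", b)) + 5
    } else {
      parts <- as.numeric(strsplit(b, "-", fixed = TRUE)[[1L]])
      if (length(parts) != 2L || any(is.na(parts))) {
        stop(sprintf("malformed age band '%s'", b), call. = FALSE)
      }
      mean(parts)
    }
  }, numeric(1L), USE.NAMES = FALSE)
}

# Width in years of an age band; the open-ended band has no ageing outflow.
band_width <- function(band) {
  vapply(band, function(b) {
    if (grepl("\\+$", b)) Inf
    else diff(as.numeric(strsplit(b, "-", fixed = TRUE)[[1L]])) + 1
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Generate a synthetic age- and sex-specific incidence table
#'
#' A deterministic stand-in for registry incidence rates: the rate surface is
#' exponential in age (doubling every `doubling_years` of age-band midpoint
#' distance from a reference band) with a constant male-to-female ratio. The
#' defaults are calibrated so that, combined with the default population,
#' about 2.1 million expected cases accrue over a 31-year horizon — the order
#' of magnitude of national colorectal-cancer projections.
#'
#' @param base_rate Female rate per 100,000 person-years at the reference
#'   band. Default 39.
#' @param reference_group Age band carrying `base_rate`. Default `"50-54"`.
#' @param doubling_years Age difference over which the rate doubles (> 0).
#'   Default 10.
#' @param male_female_ratio Multiplier applied to male rates (> 0).
#'   Default 1.3.
#' @param bands Age-band labels. Default [age_bands()].
#' @return A tibble `sex`, `age_group`, `rate` (per 100,000 person-years).
#' @export
generate_incidence <- function(base_rate = 39, reference_group = "50-54",
                               doubling_years = 10, male_female_ratio = 1.3,
                               bands = age_bands()) {
  if (base_rate < 0 || doubling_years <= 0 || male_female_ratio <= 0) {
    stop("incidence parameters must be positive (base_rate may be zero)",
         call. = FALSE)
  }
  mid <- band_midpoint(bands)
  ref <- band_midpoint(reference_group)
  female <- base_rate * 2^((mid - ref) / doubling_years)
  dplyr::bind_rows(
    tibble::tibble(sex = "male", age_group = bands,
                   rate = female * male_female_ratio),
    tibble::tibble(sex = "female", age_group = bands, rate = female)
  )
}

#' Default starting population counts
#'
#' A stylised national age pyramid of roughly 84 million persons across the
#' package's age bands, split by sex, used as the seed of the synthetic
#' population projection.
#'
#' @return A tibble `sex`, `age_group`, `count`.
#' @export
default_start_counts <- function() {
  bands <- age_bands()
  thousands <- c(13700, 6300, 5000, 5300, 5200, 5000, 5100, 6300, 6900,
                 6200, 5200, 4300, 3700, 5900)
  male_share <- c(rep(0.51, 10L), 0.49, 0.47, 0.45, 0.40)
  dplyr::bind_rows(
    tibble::tibble(sex = "male", age_group = bands,
                   count = thousands * 1000 * male_share),
    tibble::tibble(sex = "female", age_group = bands,
                   count = thousands * 1000 * (1 - male_share))
  )
}

#' Repeat fixed population counts over a horizon
#'
#' Builds a population projection in which every year carries the same
#' counts — the constant-population setting used in sensitivity analyses
#' where only the temporal risk dynamics should vary.
#'
#' @param counts Tibble `sex`, `age_group`, `count`.
#'   Default [default_start_counts()].
#' @param years Integer vector of calendar years.
#' @return A tibble `year`, `sex`, `age_group`, `count`.
#' @export
constant_population <- function(counts = default_start_counts(),
                                years = 2020:2050) {
  stopifnot(all(c("sex", "age_group", "count") %in% names(counts)))
  if (any(counts$count < 0)) stop("counts must be >= 0", call. = FALSE)
  out <- tidyr::crossing(year = as.integer(years),
                         counts[, c("sex", "age_group")])
  dplyr::left_join(out, counts, by = c("sex", "age_group"))
}

#' Generate a synthetic cohort-drift population projection
#'
#' A deterministic cohort-component stand-in for official population
#' forecasts. Each year, `count / width` persons age out of every closed
#' band into the next one, a constant entry cohort enters the youngest band,
#' and each band's result is thinned by its annual survival factor; the
#' open-ended band retains its occupants (scaled by its survival) and
#' receives the inflow from below. Persons are conserved exactly up to entry
#' and survival losses, and the default parameters produce a slowly ageing,
#' slowly growing population.
#'
#' @param start_counts Tibble `sex`, `age_group`, `count` for the first year.
#'   Default [default_start_counts()].
#' @param years Integer vector of calendar years; the first year carries
#'   `start_counts` unchanged.
#' @param survival Annual survival factor per band, recycled scalar or one
#'   value per band (applied to both sexes). Default 1 for closed bands and
#'   0.80 for the open band (a mean residence of five years past 80).
#' @param entry Persons entering the youngest band per year and sex.
#'   Default 375,000.
#' @return A tibble `year`, `sex`, `age_group`, `count`.
#' @export
generate_population <- function(start_counts = default_start_counts(),
                                years = 2020:2050, survival = NULL,
                                entry = 375000) {
  stopifnot(all(c("sex", "age_group", "count") %in% names(start_counts)))
  if (any(start_counts$count < 0)) stop("counts must be >= 0", call. = FALSE)
  bands <- unique(start_counts$age_group)
  widths <- band_width(bands)
  nb <- length(bands)
  if (nb < 2L) stop("need at least two age bands", call. = FALSE)
  if (any(is.infinite(widths[-nb]))) {
    stop("only the last age band may be open-ended", call. = FALSE)
  }
  if (is.null(survival)) survival <- c(rep(1, nb - 1L), 0.80)
  if (length(survival) == 1L) survival <- rep(survival, nb)
  if (length(survival) != nb || any(survival < 0 | survival > 1)) {
    stop("`survival` must be one factor per band, each in [0, 1]",
         call. = FALSE)
  }
  years <- as.integer(years)
  out <- vector("list", length(years))
  state <- lapply(c("male", "female"), function(sx) {
    m <- start_counts[start_counts$sex == sx, ]
    m$count[match(bands, m$age_group)]
  })
  names(state) <- c("male", "female")
  for (t in seq_along(years)) {
    for (sx in names(state)) {
      out[[t]] <- dplyr::bind_rows(
        out[[t]],
        tibble::tibble(year = years[t], sex = sx, age_group = bands,
                       count = state[[sx]]))
    }
    if (t == length(years)) break
    for (sx in names(state)) {
      cnt <- state[[sx]]
      ageing_out <- ifelse(is.finite(widths), cnt / widths, 0)
      inflow <- c(entry, ageing_out[-nb])
      nxt <- numeric(nb)
      nxt[-nb] <- survival[-nb] * (cnt[-nb] - ageing_out[-nb] + inflow[-nb])
      nxt[nb] <- survival[nb] * cnt[nb] + inflow[nb]
      state[[sx]] <- nxt
    }
  }
  dplyr::bind_rows(out)
}
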