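#' Expected migrants per generation
#'
#' Converts a diploid effective size and a per-generation migration rate
#' into the expected number of migrant individuals per generation,
#' `N * m`. With the package's rate convention (`m_xy` = fraction of
#' population y replaced by migrants from x), `N_y * m_xy` is the number
#' of x-born individuals entering y each generation. Reports
#' conventionally round this to two decimals.
#'
#' @param N diploid effective population size (of the receiving
#'   population).
#' @param m per-generation migration rate in `[0, 1)`.
#' @return `N * m`.
#' @export
migrants_per_generation <- function(N, m) {
  stopifnot(all(N >= 0), all(m >= 0 & m < 1))
  N * m
}

#' Convert generations to calendar time
#'
#' Scales a generation count by the generation time (3 years for geese)
#' and anchors it to a reference calendar year. Returns both the raw
#' years-before-present figure and the calendar year, with a BCE flag
#' and the roundings used in narrative reporting (nearest decade for
#' recent events, nearest millennium for deep ones).
#'
#' @param generations generations before present (>= 0).
#' @param generation_time_years years per generation (default 3).
#' @param present_year reference year (default 2020).
#' @return A list: `years_before_present`, `calendar_year` (signed,
#'   non-positive values are BCE), `bce`, `bce_year` (positive BCE year
#'   when `bce` is `TRUE`), `years_rounded_decade`,
#'   `bce_rounded_millennium`.
#' @export
generations_to_calendar <- function(generations, generation_time_years = 3,
                                    present_year = 2020) {
  stopifnot(generations >= 0)
  years <- generations * generation_time_years
  cal <- present_year - years
  bce <- cal <= 0
  bce_year <- if (bce) 1 - cal else NA_real_ # no year zero
  list(years_before_present = years,
       calendar_year = cal,
       bce = bce,
       bce_year = bce_year,
       years_rounded_decade = round(years / 10) * 10,
       bce_rounded_millennium = if (bce) round(bce_year / 1000) * 1000 else NA_real_)
}
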