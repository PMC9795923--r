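# Fixed 365-day (non-leap) calendar used throughout: seasonal windows are
# date-defined, so a single calendar avoids leap-day dialects.

.MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Ordinal date on the fixed 365-day calendar
#'
#' @param month Month number (1-12).
#' @param day Day of month.
#' @return Integer day of year (1-365), non-leap.
#' @examples
#' ordinal_date(3, 1)   # 1 March  -> 60
#' ordinal_date(11, 15) # 15 November -> 319
#' @export
ordinal_date <- function(month, day) {
  stopifnot(all(month >= 1L & month <= 12L), all(day >= 1L))
  cumsum(c(0L, .MONTH_DAYS))[month] + as.integer(day)
}

#' Seasonal migration windows
#'
#' The retention window for half-max estimates: 1 March-15 June (spring) and
#' 1 August-15 November (autumn), inclusive, on the 365-day calendar.
#'
#' @param season `"spring"` or `"autumn"`.
#' @return Integer vector `c(start, end)` of ordinal dates.
#' @export
season_window <- function(season) {
  season <- match.arg(season, c("spring", "autumn"))
  if (season == "spring") c(60L, 166L) else c(213L, 319L)
}

#' Curve-fitting windows per platform
#'
#' Radar smooths are fit over the seasonal windows themselves; weekly
#' abundance smooths are fit over wider windows anchored to week midpoints
#' (4 January-28 June in spring; 6 July-28 December in autumn) so the
#' seasonal rise and fall are both visible to the smoother.
#'
#' @param season `"spring"` or `"autumn"`.
#' @param platform `"radar"` or `"ebird"`.
#' @return Integer vector `c(start, end)` of ordinal dates.
#' @export
fit_window <- function(season, platform = c("radar", "ebird")) {
  season <- match.arg(season, c("spring", "autumn"))
  platform <- match.arg(platform)
  if (platform == "radar") return(season_window(season))
  if (season == "spring") c(4L, 179L) else c(187L, 362L)
}

#' Is an ordinal date inside the seasonal retention window?
#'
#' @param d Ordinal date(s).
#' @param season `"spring"` or `"autumn"`.
#' @return Logical vector.
#' @export
in_season_window <- function(d, season) {
  w <- season_window(season)
  d >= w[1] & d <= w[2]
}
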