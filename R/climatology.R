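# Climatological heat indicators: threshold-day counts, heat waves,
# monthly means, and absolute/SD-scaled anomalies.

#' Count threshold days and nights
#'
#' Counts, over a daily summary table, hot days (`tmax > 25` degC), very hot
#' days (`tmax > 30`), extremely hot days (`tmax > 35`), warm nights
#' (`tmin > 18`) and tropical nights (`tmin > 20`). All thresholds are
#' strict inequalities, so boundary values are excluded. Incomplete days
#' (where a `complete` column is `FALSE`) are excluded from the counts and
#' reported.
#'
#' @param daily Daily summary data frame with `tmax` and `tmin` (see
#'   [aggregate_daily()]); an optional logical `complete` column marks days
#'   eligible for counting.
#' @return A one-row data frame: `hot_days`, `very_hot_days`,
#'   `extremely_hot_days`, `warm_nights`, `tropical_nights`, `n_days`,
#'   `n_excluded`.
#' @examples
#' d <- data.frame(tmax = c(24.9, 25.1, 31, 36), tmin = c(15, 18.5, 20.5, 17))
#' count_threshold_days(d)
#' @export
count_threshold_days <- function(daily) {
  if (nrow(daily) == 0) {
    return(data.frame(hot_days = 0L, very_hot_days = 0L,
                      extremely_hot_days = 0L, warm_nights = 0L,
                      tropical_nights = 0L, n_days = 0L, n_excluded = 0L))
  }
  keep <- if ("complete" %in% names(daily)) daily$complete else
    rep(TRUE, nrow(daily))
  d <- daily[keep, , drop = FALSE]
  data.frame(
    hot_days = sum(d$tmax > 25),
    very_hot_days = sum(d$tmax > 30),
    extremely_hot_days = sum(d$tmax > 35),
    warm_nights = sum(d$tmin > 18),
    tropical_nights = sum(d$tmin > 20),
    n_days = nrow(d),
    n_excluded = sum(!keep)
  )
}

#' Detect heat waves
#'
#' A heat wave is a maximal run of at least `min_length` consecutive days
#' whose daily maximum temperature strictly exceeds `threshold` (defaults:
#' 3 days above 30 degC, the air-temperature threshold associated with a
#' sudden increase in mortality in European cities). Two runs separated by
#' even a single sub-threshold day are distinct waves. Dates must be
#' contiguous; a gap is an error, because a silent gap could merge or split
#' runs.
#'
#' @param dates `Date` vector, one per day, strictly increasing by one day.
#' @param tmax Daily maximum temperature, degC, aligned with `dates`.
#' @param threshold Temperature threshold, degC (strict `>`).
#' @param min_length Minimum run length in days.
#' @return Data frame with one row per wave: `start_date`, `length_days`,
#'   ordered by start. Zero rows when there is no wave.
#' @examples
#' d <- seq(as.Date("2019-06-01"), by = "day", length.out = 6)
#' detect_heat_waves(d, c(31, 32, 33, 29, 31, 31))
#' @export
detect_heat_waves <- function(dates, tmax, threshold = 30, min_length = 3L) {
  if (length(dates) != length(tmax)) {
    stop_bioheat("'dates' and 'tmax' must align", class = "bioheat_input_error")
  }
  empty <- data.frame(start_date = as.Date(character()),
                      length_days = integer())
  if (length(dates) == 0) return(empty)
  if (length(dates) > 1 && any(diff(as.integer(as.Date(dates))) != 1)) {
    stop_bioheat("dates must be contiguous (fill or split the series first)",
                 class = "bioheat_input_error")
  }
  r <- rle(tmax > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- r$values & r$lengths >= min_length
  if (!any(hit)) return(empty)
  data.frame(start_date = as.Date(dates)[starts[hit]],
             length_days = r$lengths[hit])
}

#' Anomaly of a value against a multi-year reference
#'
#' Absolute anomaly (`value - mean(reference)`, same units) and relative
#' anomaly in multiples of the reference standard deviation (sample SD,
#' n - 1 denominator). A constant reference leaves the relative anomaly
#' undefined (`NA`) while the absolute anomaly is still returned.
#'
#' @param value The statistic for the year under analysis.
#' @param reference The same statistic across reference years (length >= 2,
#'   `NA`s dropped).
#' @return List: `absolute`, `relative_sd`, `ref_mean`, `ref_sd`, `ref_n`.
#' @examples
#' anomaly(26.8, c(18, 20, 22))
#' @export
anomaly <- function(value, reference) {
  reference <- reference[!is.na(reference)]
  if (length(reference) < 2) {
    stop_bioheat("'reference' needs at least 2 non-missing values",
                 class = "bioheat_input_error")
  }
  m <- mean(reference)
  s <- stats::sd(reference)
  absolute <- value - m
  list(
    absolute = absolute,
    relative_sd = if (s > 0) absolute / s else NA_real_,
    ref_mean = m, ref_sd = s, ref_n = length(reference)
  )
}

#' Mean over valid records
#'
#' Arithmetic mean of a daily or hourly series with missing sentinels
#' (`NA`) excluded; reports how many records contributed. An all-missing or
#' empty series is an error, never a silent `NaN`.
#'
#' @param x Numeric vector.
#' @return List: `mean`, `n`.
#' @export
monthly_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    stop_bioheat("no non-missing values to average",
                 class = "bioheat_input_error")
  }
  list(mean = mean(x), n = length(x))
}
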