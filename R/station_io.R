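# Reading, validating, writing and daily aggregation of station weather
# tables, plus mortality and pollution inputs.

#' Input/output dialect for station tables
#'
#' Declares how a delimited weather file is to be interpreted. Cloud cover
#' may arrive either as a fraction in \[0, 1\] or in oktas (0-8); the unit
#' is always declared, never guessed, and oktas are converted to a fraction
#' on read. Missing values are an explicit sentinel token, never a silent
#' zero.
#'
#' @param delimiter Field delimiter.
#' @param cloud_units `"fraction"` or `"oktas"`.
#' @param na_token Sentinel string marking a missing value.
#' @return A list of class `bioheat_dialect`.
#' @export
io_dialect <- function(delimiter = ",", cloud_units = c("fraction", "oktas"),
                       na_token = "NA") {
  cloud_units <- match.arg(cloud_units)
  structure(list(delimiter = delimiter, cloud_units = cloud_units,
                 na_token = na_token),
            class = "bioheat_dialect")
}

.HOURLY_COLUMNS <- c("station_id", "timestamp", "ta", "vp", "v10", "cloud")

#' Read hourly station observations
#'
#' Reads a delimited file of station-hours (columns `station_id`,
#' `timestamp` ISO-8601, `ta` degC, `vp` hPa, `v10` m/s, `cloud`), validates
#' every row against the data-model invariants (`vp >= 0`, `v10 >= 0`,
#' cloud within its declared range, parseable timestamp), converts oktas to
#' a cloud fraction when the dialect declares them, and rejects invalid
#' rows individually. Rejected rows are reported with line numbers in the
#' `rejected` attribute and via a warning; a missing declared column or a
#' duplicated station-hour is an error.
#'
#' @param path File path.
#' @param dialect See [io_dialect()].
#' @return Data frame of valid observations ordered by station and time,
#'   with `cloud` as a fraction; attribute `rejected` holds per-row
#'   diagnostics (line and reason) for rows that failed validation.
#' @export
read_hourly <- function(path, dialect = io_dialect()) {
  if (!file.exists(path)) {
    stop_bioheat("file not found: ", path, class = "bioheat_io_error")
  }
  raw <- utils::read.table(path, header = TRUE, sep = dialect$delimiter,
                           na.strings = dialect$na_token,
                           colClasses = "character",
                           stringsAsFactors = FALSE, strip.white = TRUE)
  missing_cols <- setdiff(.HOURLY_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop_bioheat("missing required column(s): ",
                 paste(missing_cols, collapse = ", "),
                 class = "bioheat_config_error")
  }
  n <- nrow(raw)
  line <- seq_len(n) + 1L  # header is line 1
  ts <- parse_iso8601(raw$timestamp)
  num <- function(x) suppressWarnings(as.numeric(x))
  ta <- num(raw$ta); vp <- num(raw$vp); v10 <- num(raw$v10)
  cloud <- num(raw$cloud)

  reason <- rep(NA_character_, n)
  flag <- function(bad, why) {
    bad <- bad & is.na(reason)
    reason[bad] <<- why
  }
  flag(is.na(ts), "unparseable timestamp")
  flag(is.na(ta), "non-numeric ta")
  flag(is.na(vp) | vp < 0, "vp missing or negative")
  flag(is.na(v10) | v10 < 0, "v10 missing or negative")
  if (dialect$cloud_units == "oktas") {
    flag(is.na(cloud) | cloud < 0 | cloud > 8, "cloud outside 0-8 oktas")
    cloud <- cloud / 8
  } else {
    flag(is.na(cloud) | cloud < 0 | cloud > 1, "cloud outside [0,1]")
  }

  keep <- is.na(reason)
  obs <- data.frame(
    station_id = raw$station_id[keep],
    timestamp = ts[keep],
    ta = ta[keep], vp = vp[keep], v10 = v10[keep], cloud = cloud[keep],
    stringsAsFactors = FALSE
  )
  dup <- duplicated(obs[c("station_id", "timestamp")])
  if (any(dup)) {
    stop_bioheat("duplicate station-hour(s), first at line ",
                 line[keep][which(dup)[1]], class = "bioheat_io_error")
  }
  obs <- obs[order(obs$station_id, obs$timestamp), , drop = FALSE]
  rownames(obs) <- NULL
  rejected <- data.frame(line = line[!keep], reason = reason[!keep])
  if (nrow(rejected) > 0) {
    warning(sprintf("read_hourly: rejected %d of %d row(s); see attr(, \"rejected\")",
                    nrow(rejected), n), call. = FALSE)
  }
  attr(obs, "rejected") <- rejected
  obs
}

#' Write hourly observations
#'
#' Inverse of [read_hourly()]: writes the observation table with ISO-8601
#' UTC timestamps and cloud cover in the dialect's declared units, so that a
#' write-then-read round trip is the identity.
#'
#' @param obs Observation data frame as returned by [read_hourly()] or
#'   [generate_weather()].
#' @param path Output file path.
#' @param dialect See [io_dialect()].
#' @return `path`, invisibly.
#' @export
write_hourly <- function(obs, path, dialect = io_dialect()) {
  out <- obs[.HOURLY_COLUMNS]
  out$timestamp <- format(obs$timestamp, "%Y-%m-%dT%H:%M:%S+00:00",
                          tz = "UTC")
  if (dialect$cloud_units == "oktas") {
    out$cloud <- obs$cloud * 8
  }
  utils::write.table(out, path, sep = dialect$delimiter, row.names = FALSE,
                     quote = FALSE, na = dialect$na_token)
  invisible(path)
}

#' Aggregate hourly observations to daily summaries
#'
#' Collapses station-hours to one row per station and UTC date: `tmax`,
#' `tmin`, `tavg` over all valid hours, the same statistics for a matched
#' hourly UTCI series (`utci_avg`, `utci_max`), and the midday variants
#' (`ta_12`, `utci_12`) taken from the single `midday_hour` UTC record
#' (12 UTC by default, i.e. 14:00 Central European summer time). Days with
#' fewer than `min_hours` valid hours are flagged `complete = FALSE`; a day
#' without a midday record gets `NA` midday fields rather than an imputed
#' value.
#'
#' @param obs Hourly observations (see [read_hourly()]).
#' @param utci Optional numeric vector of hourly UTCI values aligned with
#'   `obs` rows.
#' @param midday_hour Hour of day (UTC) defining the midday record.
#' @param min_hours Minimum valid hours for a complete day.
#' @return Data frame with one row per station-date: `station_id`, `date`,
#'   `tmax`, `tmin`, `tavg`, `ta_12`, `utci_avg`, `utci_max`, `utci_12`,
#'   `n_hours`, `complete`.
#' @export
aggregate_daily <- function(obs, utci = NULL, midday_hour = 12L,
                            min_hours = 18L) {
  if (!is.null(utci) && length(utci) != nrow(obs)) {
    stop_bioheat("'utci' must align with 'obs' rows",
                 class = "bioheat_input_error")
  }
  date <- as.Date(obs$timestamp, tz = "UTC")
  hour <- as.POSIXlt(obs$timestamp, tz = "UTC")$hour
  key <- paste(obs$station_id, date)
  idx <- split(seq_len(nrow(obs)), key)
  rows <- lapply(idx, function(i) {
    ta <- obs$ta[i]
    mid <- i[hour[i] == midday_hour]
    mid1 <- if (length(mid) > 0) mid[1] else NA_integer_
    u <- if (is.null(utci)) rep(NA_real_, length(i)) else utci[i]
    data.frame(
      station_id = obs$station_id[i[1]],
      date = date[i[1]],
      tmax = max(ta), tmin = min(ta), tavg = mean(ta),
      ta_12 = if (is.na(mid1)) NA_real_ else obs$ta[mid1],
      utci_avg = if (is.null(utci)) NA_real_ else mean(u),
      utci_max = if (is.null(utci)) NA_real_ else max(u),
      utci_12 = if (is.na(mid1) || is.null(utci)) NA_real_ else utci[mid1],
      n_hours = length(i),
      stringsAsFactors = FALSE
    )
  })
  daily <- do.call(rbind, rows)
  daily <- daily[order(daily$station_id, daily$date), , drop = FALSE]
  rownames(daily) <- NULL
  daily$complete <- daily$n_hours >= min_hours
  daily
}

#' Read a monthly mortality table
#'
#' Columns `city_id`, `year`, `month`, `deaths`, `population`; missing death
#' counts are permitted (the sentinel token) and stay `NA` -- they are
#' excluded from reference means downstream, never imputed.
#'
#' @inheritParams read_hourly
#' @return Data frame with the columns above.
#' @export
read_mortality <- function(path, dialect = io_dialect()) {
  if (!file.exists(path)) {
    stop_bioheat("file not found: ", path, class = "bioheat_io_error")
  }
  tab <- utils::read.table(path, header = TRUE, sep = dialect$delimiter,
                           na.strings = dialect$na_token,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("city_id", "year", "month", "deaths", "population")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop_bioheat("missing required column(s): ",
                 paste(missing_cols, collapse = ", "),
                 class = "bioheat_config_error")
  }
  if (any(tab$deaths < 0, na.rm = TRUE) ||
      any(tab$population <= 0, na.rm = TRUE)) {
    stop_bioheat("deaths must be >= 0 and population > 0",
                 class = "bioheat_io_error")
  }
  tab[need]
}
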