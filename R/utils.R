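# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bioheat <- function(..., class = "bioheat_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_bioheat("'", name, "' must be finite numeric",
                 class = "bioheat_input_error")
  }
  invisible(x)
}

# saturation vapour pressure over water, hPa (Magnus form)
saturation_vp <- function(ta) {
  6.105 * exp(17.27 * ta / (237.7 + ta))
}

#' Vapour pressure from relative humidity
#'
#' Convenience conversion from relative humidity to water-vapour pressure
#' using the Magnus saturation formula, for feeding [compute_utci()] and the
#' heat-balance functions, which take vapour pressure directly.
#'
#' @param ta Air temperature, degrees C.
#' @param rh Relative humidity, percent (0-100).
#' @return Vapour pressure in hPa.
#' @examples
#' vp_from_rh(25, 50)  # about 15.8 hPa
#' @export
vp_from_rh <- function(ta, rh) {
  assert_finite(ta, "ta")
  assert_finite(rh, "rh")
  if (any(rh < 0 | rh > 100)) {
    stop_bioheat("'rh' must lie in [0, 100]", class = "bioheat_input_error")
  }
  saturation_vp(ta) * rh / 100
}

# parse ISO-8601 timestamps with explicit offset ("Z", "+02:00", "+0200");
# returns POSIXct in UTC, NA where unparseable
parse_iso8601 <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("Z$", "+0000", x)
  # drop the colon inside a numeric offset so strptime's %z accepts it
  x <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x)
  # bare timestamps (no offset) are taken as UTC
  bare <- !grepl("[+-][0-9]{4}$", x)
  x[bare] <- paste0(x[bare], "+0000")
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S%z")
  retry <- is.na(out)
  if (any(retry)) {
    out[retry] <- as.POSIXct(x[retry], tz = "UTC", format = "%Y-%m-%d %H:%M%z")
  }
  out
}
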