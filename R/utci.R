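# Universal Thermal Climate Index: operational polynomial approximation and
# the assessment-scale category bands.

# cache for the coefficient table (loaded once per session)
.utci_env <- new.env(parent = emptyenv())

# number of terms and coefficient checksum of the shipped table; guards
# against a corrupted or truncated data file
.UTCI_N_TERMS <- 210L
.UTCI_COEF_SUM <- 1.39064156557505

utci_coefficients <- function() {
  if (!is.null(.utci_env$coef)) {
    return(.utci_env$coef)
  }
  path <- system.file("extdata", "utci_polynomial_coefficients.csv",
                      package = "bioheat", mustWork = TRUE)
  tab <- utils::read.csv(path, colClasses = c(rep("integer", 4), "numeric"))
  if (nrow(tab) != .UTCI_N_TERMS ||
      abs(sum(tab$coefficient) - .UTCI_COEF_SUM) > 1e-10) {
    stop_bioheat("UTCI coefficient table failed its checksum",
                 class = "bioheat_data_error")
  }
  .utci_env$coef <- tab
  tab
}

# validity domain of the polynomial approximation
.UTCI_DOMAIN <- list(
  ta    = c(-50, 50),   # degC
  v10   = c(0.5, 17),   # m/s at 10 m
  dtmrt = c(-30, 70),   # tmrt - ta, degC
  vp    = c(0, 50)      # hPa
)

#' Compute the Universal Thermal Climate Index
#'
#' Evaluates the operational sixth-order polynomial approximation of UTCI
#' from air temperature, mean radiant temperature, 10-m wind speed and
#' water-vapour pressure, and classifies the result on the UTCI assessment
#' scale. Inputs outside the approximation's validity domain (`ta` in
#' \[-50, 50\] degC, `v10` in \[0.5, 17\] m/s, `tmrt - ta` in \[-30, 70\]
#' degC, `vp` up to 50 hPa) are clipped to the nearest domain edge and the
#' record is flagged; station data routinely contain calm winds below
#' 0.5 m/s, which would otherwise have to be rejected.
#'
#' @param ta Air temperature at 2 m, degrees C.
#' @param tmrt Mean radiant temperature, degrees C
#'   (see [mean_radiant_temp()]).
#' @param v10 Wind speed at 10 m, m/s.
#' @param vp Water-vapour pressure, hPa ([vp_from_rh()] converts from
#'   relative humidity).
#' @return A data frame with one row per input: `utci` (degrees C),
#'   `category` (ordered factor, see [classify_stress()]) and `clamped`
#'   (logical, `TRUE` where any input was clipped).
#' @examples
#' compute_utci(ta = 30, tmrt = 50, v10 = 2, vp = 21)
#' @seealso [classify_stress()] for the category bands alone.
#' @export
compute_utci <- function(ta, tmrt, v10, vp) {
  assert_finite(ta, "ta")
  assert_finite(tmrt, "tmrt")
  assert_finite(v10, "v10")
  assert_finite(vp, "vp")
  n <- max(length(ta), length(tmrt), length(v10), length(vp))
  ta <- rep_len(ta, n); tmrt <- rep_len(tmrt, n)
  v10 <- rep_len(v10, n); vp <- rep_len(vp, n)

  clip <- function(x, lim) pmin(pmax(x, lim[1]), lim[2])
  outside <- function(x, lim) x < lim[1] | x > lim[2]
  ta_c <- clip(ta, .UTCI_DOMAIN$ta)
  v_c  <- clip(v10, .UTCI_DOMAIN$v10)
  d_c  <- clip(tmrt - ta_c, .UTCI_DOMAIN$dtmrt)
  vp_c <- clip(vp, .UTCI_DOMAIN$vp)
  clamped <- outside(ta, .UTCI_DOMAIN$ta) | outside(v10, .UTCI_DOMAIN$v10) |
    outside(tmrt - ta, .UTCI_DOMAIN$dtmrt) | outside(vp, .UTCI_DOMAIN$vp)

  utci <- utci_polynomial(ta_c, d_c, v_c, vp_c)
  data.frame(
    utci = utci,
    category = classify_stress(utci),
    clamped = clamped
  )
}

# raw polynomial evaluation on already-clipped inputs; pa in kPa internally
utci_polynomial <- function(ta, dtmrt, va, vp) {
  tab <- utci_coefficients()
  pa <- vp / 10
  offset <- numeric(length(ta))
  for (r in seq_len(nrow(tab))) {
    offset <- offset + tab$coefficient[r] *
      ta^tab$ta_pow[r] * va^tab$va_pow[r] *
      dtmrt^tab$dtmrt_pow[r] * pa^tab$pa_pow[r]
  }
  ta + offset
}

# band edges (right-closed) and labels of the UTCI assessment scale as used
# here: the full cold side is collapsed into a single below-scale class
.UTCI_BREAKS <- c(-Inf, 0, 9, 26, 32, 38, 46, Inf)
.UTCI_LABELS <- c("below_scale", "SCS", "NTS", "MHS", "SHS", "VSHS",
                  "above_scale")

#' Classify UTCI into thermal-stress categories
#'
#' Maps UTCI values onto the assessment-scale bands used for heat-stress
#' reporting: slight cold stress (SCS, 0.1-9.0 degC), no thermal stress
#' (NTS, 9.1-26.0), moderate heat stress (MHS, 26.1-32.0), strong heat
#' stress (SHS, 32.1-38.0) and very strong heat stress (VSHS, 38.1-46.0).
#' Bands are half-open on the left and closed on the right, so a value of
#' exactly 26.0 is NTS and 26.1 is MHS, reproducing the printed one-decimal
#' band edges. Values at or below 0 degC are reported as a single
#' `below_scale` class (colder than SCS); values above 46 as `above_scale`.
#'
#' @param utci UTCI values, degrees C.
#' @return Ordered factor with levels `below_scale < SCS < NTS < MHS < SHS
#'   < VSHS < above_scale`.
#' @examples
#' classify_stress(c(30, 26, 26.05, 38.5))
#' @export
classify_stress <- function(utci) {
  assert_finite(utci, "utci")
  cut(utci, breaks = .UTCI_BREAKS, labels = .UTCI_LABELS,
      right = TRUE, ordered_result = TRUE)
}

#' Heat-stress day categories from daily UTCI values
#'
#' Convenience wrapper: classify one UTCI value per day (typically the
#' midday value or the daily maximum) and report which days carry strong
#' (SHS) or very strong (VSHS) heat stress.
#'
#' @param utci_daily One UTCI value per day, degrees C.
#' @return Logical vector, `TRUE` for SHS or VSHS days.
#' @export
is_strong_heat_day <- function(utci_daily) {
  classify_stress(utci_daily) %in% c("SHS", "VSHS")
}
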