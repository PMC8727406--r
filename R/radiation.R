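# Solar geometry, global radiation under cloud, and mean radiant temperature
# (Tmrt) -- the radiative inputs to UTCI and the human heat balance.

#' Radiation model constants
#'
#' All empirical constants of the radiation chain in one place, so a run can
#' log them and a user can override any of them. Defaults: solar constant
#' 1361 W/m2; broadband clear-sky transmittance 0.75 per unit air mass;
#' Kasten-Czeplak cloud attenuation `1 - 0.75 * N^3.4`; Brunt clear-sky
#' emissivity `0.605 + 0.048 * sqrt(vp)` with a Crawford-Duchon cloud
#' correction; short-wave albedo 0.3 and long-wave emissivity 0.97 of a
#' clothed person.
#'
#' @param solar_constant Top-of-atmosphere irradiance, W/m2.
#' @param transmittance Clear-sky broadband transmittance per unit relative
#'   air mass (dimensionless, 0-1).
#' @param cloud_coef,cloud_exponent Cloud attenuation `1 - cloud_coef *
#'   N^cloud_exponent` applied to clear-sky irradiance.
#' @param brunt_a,brunt_b Clear-sky emissivity `brunt_a + brunt_b *
#'   sqrt(vp)` (vp in hPa).
#' @param albedo Short-wave albedo of the clothed person (dimensionless).
#' @param emissivity_person Long-wave emissivity of the person.
#' @return Named list of constants.
#' @export
radiation_constants <- function(solar_constant = 1361,
                                transmittance = 0.75,
                                cloud_coef = 0.75,
                                cloud_exponent = 3.4,
                                brunt_a = 0.605,
                                brunt_b = 0.048,
                                albedo = 0.3,
                                emissivity_person = 0.97) {
  as.list(environment())
}

#' Solar position
#'
#' Solar elevation and azimuth for a site and UTC timestamp, from the
#' standard low-precision astronomical algorithm (fractional-year Fourier
#' series for declination and the equation of time, then the hour-angle
#' formula). Accuracy is a few tenths of a degree, ample for irradiance
#' modelling.
#'
#' @param latitude Degrees north (-90 to 90).
#' @param longitude Degrees east.
#' @param timestamp `POSIXct` in UTC (vectorised).
#' @return Data frame with `elevation` and `azimuth` in degrees (azimuth
#'   clockwise from north).
#' @examples
#' noon <- as.POSIXct("2019-06-21 11:00:00", tz = "UTC")
#' solar_position(52.23, 21.01, noon)
#' @export
solar_position <- function(latitude, longitude, timestamp) {
  if (any(abs(latitude) > 90)) {
    stop_bioheat("|latitude| must be <= 90", class = "bioheat_input_error")
  }
  t <- as.POSIXlt(timestamp, tz = "UTC")
  doy <- t$yday + 1
  hour <- t$hour + t$min / 60 + t$sec / 3600
  # fractional year, radians (Spencer)
  g <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)
  # declination, radians
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  # equation of time, minutes
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  tst <- hour * 60 + eqtime + 4 * longitude        # true solar time, min
  ha <- (tst / 4 - 180) * pi / 180                 # hour angle, radians
  lat <- latitude * pi / 180
  sin_el <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  sin_el <- pmin(pmax(sin_el, -1), 1)
  elevation <- asin(sin_el)
  cos_az <- (sin(decl) - sin(lat) * sin_el) / (cos(lat) * cos(elevation))
  cos_az <- pmin(pmax(cos_az, -1), 1)
  azimuth <- acos(cos_az)
  azimuth <- ifelse(ha > 0, 2 * pi - azimuth, azimuth)
  data.frame(elevation = elevation * 180 / pi,
             azimuth = azimuth * 180 / pi)
}

#' Global solar irradiance under cloud
#'
#' Clear-sky global irradiance from a one-parameter transmittance model,
#' `S0 * tau^(1/sin h) * sin h`, attenuated for total cloud cover with the
#' Kasten-Czeplak factor `1 - 0.75 * N^3.4`. Zero below the horizon.
#'
#' @param elevation Solar elevation, degrees.
#' @param cloud Total cloud cover as a fraction in \[0, 1\].
#' @param constants See [radiation_constants()].
#' @return Global irradiance on the horizontal, W/m2.
#' @export
global_radiation <- function(elevation, cloud,
                             constants = radiation_constants()) {
  if (any(cloud < 0 | cloud > 1, na.rm = TRUE)) {
    stop_bioheat("'cloud' must lie in [0, 1]", class = "bioheat_input_error")
  }
  sin_h <- sin(pmax(elevation, 0) * pi / 180)
  clear <- ifelse(
    elevation > 0,
    constants$solar_constant * constants$transmittance^(1 / sin_h) * sin_h,
    0
  )
  clear * (1 - constants$cloud_coef * cloud^constants$cloud_exponent)
}

# projected-area factor of a standing person as a function of solar
# elevation (degrees); empirical fit used in outdoor radiation modelling
projected_area_factor <- function(elevation) {
  el <- pmax(elevation, 0)
  0.308 * cos(pi / 180 * el * (0.998 - el^2 / 50000))
}

#' Mean radiant temperature
#'
#' Tmrt of a standing person outdoors, from absorbed short-wave radiation
#' and sky/ground long-wave exchange. Down-welling long-wave uses a Brunt
#' clear-sky emissivity in vapour pressure with a Crawford-Duchon cloud
#' correction (`eps = N + (1 - N) * eps_clear`), so an overcast sky radiates
#' as a black body at air temperature; the ground is taken as a black body
#' at air temperature. Short-wave absorption uses the elevation-dependent
#' projected-area factor of a standing person and the person's albedo.
#' Under an overcast night sky this construction gives Tmrt equal to air
#' temperature, the enclosure limit.
#'
#' @param ta Air temperature, degrees C.
#' @param vp Vapour pressure, hPa.
#' @param cloud Total cloud cover, fraction in \[0, 1\].
#' @param kglob Global irradiance, W/m2 (see [global_radiation()]).
#' @param elevation Solar elevation, degrees.
#' @param constants See [radiation_constants()].
#' @return Tmrt, degrees C.
#' @examples
#' mean_radiant_temp(ta = 20, vp = 15, cloud = 1, kglob = 0, elevation = -10)
#' @export
mean_radiant_temp <- function(ta, vp, cloud, kglob, elevation,
                              constants = radiation_constants()) {
  if (any(kglob < 0, na.rm = TRUE)) {
    stop_bioheat("'kglob' must be >= 0", class = "bioheat_input_error")
  }
  sigma <- 5.670374419e-8
  ta_k <- ta + 273.15
  eps_clear <- pmin(constants$brunt_a + constants$brunt_b * sqrt(pmax(vp, 0)), 1)
  eps_sky <- cloud + (1 - cloud) * eps_clear
  l_down <- eps_sky * sigma * ta_k^4
  l_up <- sigma * ta_k^4
  sw_abs <- (1 - constants$albedo) * projected_area_factor(elevation) * kglob
  flux <- 0.5 * l_down + 0.5 * l_up + sw_abs / constants$emissivity_person
  (flux / sigma)^0.25 - 273.15
}
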