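# Synthetic Central European June weather and mortality with the
# statistical structure the downstream analysis assumes.

#' Synthetic weather scenario
#'
#' Describes one station-month of synthetic hourly weather: a mean June
#' temperature level, a diurnal cycle (minimum near 04, maximum near 14
#' local solar time), a day-level AR(1) anomaly giving day-to-day weather
#' variability, and optional multi-day heat-wave windows that lift all
#' hours of the affected days by a fixed amplitude. Defaults emulate a warm
#' Central European June (monthly mean near 21-23 degC) with two embedded
#' heat waves -- a seven-day wave starting on day 10 and a three-day wave
#' starting on day 25 -- whose daily maxima exceed 30 degC.
#'
#' @param latitude,longitude Site coordinates, degrees.
#' @param days Number of days to generate.
#' @param base_mean_ta Monthly mean air temperature, degC.
#' @param diurnal_amplitude Peak-to-trough amplitude of the diurnal cycle,
#'   degC.
#' @param ar1_coefficient Day-level AR(1) coefficient in \[0, 1).
#' @param noise_sd Standard deviation of the daily AR(1) innovations, degC.
#' @param heat_wave_windows List of `c(start_day, length, amplitude)`
#'   triples; each adds `amplitude` degC to every hour of the windowed days.
#' @param mean_vp,mean_v10,mean_cloud Means of vapour pressure (hPa), 10-m
#'   wind (m/s) and cloud fraction.
#' @param start_date First day (gives timestamps their calendar position).
#' @param station_id Station label carried into the output.
#' @param seed Integer seed; identical scenarios generate identical data.
#' @return A list of class `weather_scenario`.
#' @export
weather_scenario <- function(latitude = 52.2, longitude = 21.0, days = 30L,
                             base_mean_ta = 21, diurnal_amplitude = 9,
                             ar1_coefficient = 0.6, noise_sd = 1.2,
                             heat_wave_windows = list(c(10, 7, 7),
                                                      c(25, 3, 7)),
                             mean_vp = 15, mean_v10 = 3, mean_cloud = 0.4,
                             start_date = as.Date("2019-06-01"),
                             station_id = "SYN01", seed = 1L) {
  sc <- as.list(environment())
  if (days < 1) stop_bioheat("'days' must be >= 1",
                             class = "bioheat_input_error")
  if (ar1_coefficient < 0 || ar1_coefficient >= 1) {
    stop_bioheat("'ar1_coefficient' must lie in [0, 1)",
                 class = "bioheat_input_error")
  }
  for (w in heat_wave_windows) {
    if (length(w) != 3 || w[2] < 1 || w[3] < 0 ||
        w[1] < 1 || w[1] + w[2] - 1 > days) {
      stop_bioheat("heat-wave windows must be c(start, length >= 1, ",
                   "amplitude >= 0) within [1, days]",
                   class = "bioheat_input_error")
    }
  }
  structure(sc, class = "weather_scenario")
}

# diurnal shape: -1 at 04 local solar time, +1 at 14, sinusoidal in between
# (10-h rise, 14-h fall)
diurnal_shape <- function(hour_local) {
  h <- hour_local %% 24
  rise <- h >= 4 & h < 14
  phase <- ifelse(rise,
                  pi * (h - 4) / 10 - pi / 2,
                  pi / 2 + pi * ((h - 14) %% 24) / 14)
  sin(phase)
}

#' Generate synthetic hourly weather
#'
#' Expands a [weather_scenario()] into hourly observations. Air temperature
#' is `base_mean_ta + diurnal + AR(1) day anomaly + heat-wave offset`; the
#' day anomaly is shared by all hours of a day so the diurnal shape is
#' preserved. Vapour pressure is lognormal around `mean_vp`, capped below
#' saturation at the hour's temperature; wind is lognormal around
#' `mean_v10`; cloud is Beta-distributed around `mean_cloud`. All draws
#' come from deterministic sub-streams of the scenario seed, so the same
#' scenario always yields the same series.
#'
#' @param scenario A [weather_scenario()].
#' @return Hourly observation data frame (`station_id`, `timestamp`, `ta`,
#'   `vp`, `v10`, `cloud`), 24 rows per day, suitable for [compute_utci()]
#'   and [aggregate_daily()].
#' @export
generate_weather <- function(scenario) {
  stopifnot(inherits(scenario, "weather_scenario"))
  sc <- scenario
  n_days <- as.integer(sc$days)
  n <- n_days * 24L

  draw <- function(offset, expr) {
    # deterministic sub-stream per variable; restores the global RNG state
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else rm(".Random.seed", envir = globalenv()), add = TRUE)
    set.seed((as.integer(sc$seed) %% 150000000L) * 13L + offset)
    expr()
  }

  anom <- draw(1L, function() {
    eps <- stats::rnorm(n_days, 0, sc$noise_sd)
    a <- numeric(n_days)
    a[1] <- eps[1]
    if (n_days > 1) {
      for (d in 2:n_days) a[d] <- sc$ar1_coefficient * a[d - 1] + eps[d]
    }
    a
  })

  day <- rep(seq_len(n_days), each = 24L)
  hour_utc <- rep(0:23, n_days)
  hour_local <- hour_utc + sc$longitude / 15  # local solar time

  wave <- numeric(n_days)
  for (w in sc$heat_wave_windows) {
    idx <- seq(w[1], w[1] + w[2] - 1)
    wave[idx] <- wave[idx] + w[3]
  }

  # centre the diurnal shape so the daily mean equals base_mean_ta exactly
  shape <- diurnal_shape(hour_local)
  shape <- shape - mean(diurnal_shape((0:23) + sc$longitude / 15))
  ta <- sc$base_mean_ta + sc$diurnal_amplitude / 2 * shape +
    anom[day] + wave[day]

  vp <- draw(2L, function() {
    sdlog <- 0.15
    stats::rlnorm(n, log(sc$mean_vp) - sdlog^2 / 2, sdlog)
  })
  vp <- pmin(vp, 0.97 * saturation_vp(ta))

  v10 <- draw(3L, function() {
    sdlog <- 0.4
    stats::rlnorm(n, log(sc$mean_v10) - sdlog^2 / 2, sdlog)
  })

  cloud <- draw(4L, function() {
    m <- min(max(sc$mean_cloud, 0.02), 0.98)
    shape <- 4  # concentration of the Beta draw
    stats::rbeta(n, m * shape, (1 - m) * shape)
  })

  timestamp <- as.POSIXct(sc$start_date, tz = "UTC") +
    ((day - 1) * 24 + hour_utc) * 3600
  data.frame(
    station_id = sc$station_id,
    timestamp = timestamp,
    ta = ta, vp = vp, v10 = v10, cloud = cloud,
    stringsAsFactors = FALSE
  )
}

#' Synthetic mortality scenario
#'
#' Daily all-cause death counts follow a Poisson baseline, multiplied by
#' `relative_risk` on days classified as strong or very strong heat stress.
#' Defaults describe a city of 800,000 with 30 expected deaths per day and
#' a heat-day relative risk of 1.5.
#'
#' @param population City population, persons.
#' @param baseline_daily_deaths Expected deaths per day off heat days.
#' @param relative_risk Multiplicative factor on SHS/VSHS days (>= 0).
#' @param seed Integer seed.
#' @return A list of class `mortality_scenario`.
#' @export
mortality_scenario <- function(population = 800000,
                               baseline_daily_deaths = 30,
                               relative_risk = 1.5, seed = 1L) {
  if (baseline_daily_deaths <= 0) {
    stop_bioheat("'baseline_daily_deaths' must be > 0",
                 class = "bioheat_input_error")
  }
  if (relative_risk < 0) {
    stop_bioheat("'relative_risk' must be >= 0",
                 class = "bioheat_input_error")
  }
  structure(as.list(environment()), class = "mortality_scenario")
}

#' Generate synthetic daily death counts
#'
#' `deaths_d ~ Poisson(baseline * relative_risk^[day d is SHS or VSHS])`,
#' seeded and reproducible.
#'
#' @param daily_categories One thermal-stress category per day (factor or
#'   character; levels as in [classify_stress()]).
#' @param scenario A [mortality_scenario()].
#' @return Integer vector of daily death counts.
#' @export
generate_mortality <- function(daily_categories, scenario) {
  stopifnot(inherits(scenario, "mortality_scenario"))
  stress <- as.character(daily_categories) %in% c("SHS", "VSHS")
  lambda <- scenario$baseline_daily_deaths *
    scenario$relative_risk^as.numeric(stress)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(scenario$seed)
  stats::rpois(length(lambda), lambda)
}
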