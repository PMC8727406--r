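# Physiological heat strain: the human heat balance (net heat storage S),
# heart rate, sultriness index, and daily hour budgets.

#' Person configuration for the heat-balance model
#'
#' Fixes the physiological assumptions: metabolic heat production `M`
#' (default 135 W/m2, a person walking 4 km/h) and clothing state, which
#' selects the empirical evaporation coefficient `k` of the maximum-
#' evaporation formula (7.0 clothed, 11.7 naked).
#'
#' @param metabolic_rate Metabolic heat production, W/m2 (> 0).
#' @param clothed Logical; `TRUE` selects `k = 7.0`, `FALSE` `k = 11.7`.
#' @param albedo Short-wave albedo of the (clothed) body surface.
#' @return List of class `person_config` with fields `metabolic_rate`,
#'   `clothed`, `k`, `albedo`.
#' @export
person_config <- function(metabolic_rate = 135, clothed = TRUE,
                          albedo = 0.3) {
  if (metabolic_rate <= 0) {
    stop_bioheat("'metabolic_rate' must be > 0",
                 class = "bioheat_input_error")
  }
  structure(list(metabolic_rate = metabolic_rate, clothed = clothed,
                 k = if (clothed) 7.0 else 11.7, albedo = albedo),
            class = "person_config")
}

#' Heart rate under heat load
#'
#' The Fuller-Brouha regression of heart rate on metabolic rate, air
#' temperature and vapour pressure:
#' `HR = 22.4 + 0.18 * M + 0.25 * (5 * ta + 2.66 * vp)` (beats/min).
#' 90 beats/min is the conventional warning level for circulatory overload.
#'
#' @param M Metabolic heat production, W/m2.
#' @param ta Air temperature, degC.
#' @param vp Vapour pressure, hPa.
#' @return Heart rate, beats per minute.
#' @examples
#' heart_rate(135, 30, 20)  # 97.5
#' @export
heart_rate <- function(M, ta, vp) {
  assert_finite(M, "M"); assert_finite(ta, "ta"); assert_finite(vp, "vp")
  22.4 + 0.18 * M + 0.25 * (5 * ta + 2.66 * vp)
}

#' Wind speed at body height
#'
#' Converts 10-m station wind to the 1.2-m level the surface-exchange
#' formulas need, with a neutral logarithmic profile over short grass
#' (roughness length 0.01 m), a factor of about 0.69.
#'
#' @param v10 Wind speed at 10 m, m/s.
#' @param height Target height, m.
#' @param roughness Roughness length, m.
#' @return Wind speed at `height`, m/s.
#' @export
wind_at_height <- function(v10, height = 1.2, roughness = 0.01) {
  v10 * log(height / roughness) / log(10 / roughness)
}

# mean skin temperature, degC: empirical linear response to air
# temperature, radiant load and metabolic rate (constants documented in the
# methods vignette; stands in for the undisclosed physiological model)
skin_temperature <- function(ta, tmrt, M) {
  26.0 + 0.21 * ta + 0.02 * tmrt + 0.01 * M
}

#' Human heat balance
#'
#' Evaluates the heat-balance components of a person outdoors for each
#' station-hour: metabolic production `M`; radiation balance `Q`
#' (long-wave exchange with the solar-inclusive mean radiant temperature at
#' skin temperature); convection `C = hc * (ta - Tsk)` with
#' `hc = 8.3 * v1.2^0.6`; respiratory loss `Res` (latent and sensible, in
#' `ta` and `vp`, never a gain); and evaporation `E`, the sweat evaporation
#' required to balance the other components, bounded in magnitude by the
#' maximum evaporation `Emax = k * v1.2 * 0.6 * (56 - vp)` the air can
#' absorb. Sweating efficiency falls as the required fraction of `Emax`
#' (the skin wettedness `w = Ereq/Emax`) rises: the evaporation realised is
#' `Ereq * (1 - w/2)`, capped at `Emax`, so some heat storage accumulates
#' whenever sweating is demanded and grows quadratically with the demand.
#' The residual is the net heat storage `S = M + Q + E + C + Res` (exact by
#' construction); sustained `S > 15` W/m2 marks overheating risk. Sign
#' convention: gains positive, losses negative.
#'
#' @param obs Hourly observations (`ta`, `vp`, `v10`; see [read_hourly()]).
#' @param tmrt Mean radiant temperature per hour, degC (see
#'   [mean_radiant_temp()]).
#' @param person A [person_config()].
#' @return Data frame with one row per hour: `M`, `Q`, `E`, `C`, `Res`,
#'   `S` (all W/m2), `skin_temperature` (degC), `ereq`, `emax` (W/m2,
#'   diagnostics feeding [sultriness_index()]), and `overheating`
#'   (`S > 15`).
#' @export
heat_balance <- function(obs, tmrt, person = person_config()) {
  if (length(tmrt) != nrow(obs)) {
    stop_bioheat("'tmrt' must align with 'obs' rows",
                 class = "bioheat_input_error")
  }
  sigma <- 5.670374419e-8
  eps_p <- 0.97
  M <- person$metabolic_rate
  ta <- obs$ta; vp <- obs$vp
  v12 <- wind_at_height(obs$v10)

  tsk <- skin_temperature(ta, tmrt, M)
  Q <- eps_p * sigma * ((tmrt + 273.15)^4 - (tsk + 273.15)^4)
  hc <- 8.3 * pmax(v12, 0.1)^0.6
  C <- hc * (ta - tsk)
  Res <- -pmax(0.0014 * M * (34 - ta) + 1.72e-5 * M * (5867 - 100 * vp), 0)

  ereq <- M + Q + C + Res          # non-evaporative net gain
  emax <- person$k * v12 * 0.6 * (56 - vp)
  # realised evaporation: demand scaled by the wettedness efficiency
  # (1 - w/2), never more than the air can absorb
  w <- ifelse(ereq > 0 & emax > 0, pmin(ereq / emax, 1), 0)
  E <- ifelse(ereq > 0 & emax > 0,
              -pmin(ereq * (1 - w / 2), emax), 0)
  S <- M + Q + E + C + Res
  data.frame(M = M, Q = Q, E = E, C = C, Res = Res, S = S,
             skin_temperature = tsk, ereq = ereq, emax = emax,
             overheating = S > 15)
}

#' Sultriness index
#'
#' Ratio of the evaporation required for heat equilibrium (`Ereq = M + Q +
#' C + Res`) to the maximum evaporation possible in the actual air
#' (`Emax = k * v * 0.6 * (56 - vp)`, wind at 1.2 m), as a percentage:
#' `HSI = 100 * Ereq / Emax`. When no evaporation is required
#' (`Ereq <= 0`) the index is 0; when the demand meets or exceeds what the
#' air can absorb (including saturated air, `Emax <= 0`) it is capped at
#' 100. Values above 30 indicate intensive sultriness. Accepts either a
#' flux table from [heat_balance()] (which carries `ereq`) or a raw `ereq`
#' vector.
#'
#' @param fluxes Output of [heat_balance()], or a numeric `Ereq` vector
#'   (W/m2).
#' @param v12 Wind speed at 1.2 m, m/s (see [wind_at_height()]).
#' @param vp Vapour pressure, hPa.
#' @param k Evaporation coefficient (7.0 clothed, 11.7 naked).
#' @return HSI in percent, within \[0, 100\].
#' @examples
#' sultriness_index(84, v12 = 1, vp = 16, k = 7)  # Emax = 168, HSI = 50
#' @export
sultriness_index <- function(fluxes, v12, vp, k = 7.0) {
  ereq <- if (is.data.frame(fluxes)) fluxes$ereq else fluxes
  if (any(v12 < 0)) {
    stop_bioheat("'v12' must be >= 0", class = "bioheat_input_error")
  }
  emax <- k * v12 * 0.6 * (56 - vp)
  hsi <- ifelse(ereq <= 0, 0,
                ifelse(emax <= 0, 100, 100 * ereq / emax))
  pmin(hsi, 100)
}

#' Daily heat-strain hour budget
#'
#' Counts, for one day's aligned hourly series, the hours of heat stress
#' time (HST, UTCI > 26 degC), heat recovery time (HRT, UTCI < 18 degC),
#' net heat storage above 15 W/m2, heart rate above 90 beats/min and
#' sultriness above 30 percent. All thresholds are strict, so the comfort
#' band 18-26 degC is the exact complement of HST + HRT.
#'
#' @param utci Hourly UTCI, degC.
#' @param s Hourly net heat storage, W/m2.
#' @param hr Hourly heart rate, beats/min.
#' @param hsi Hourly sultriness index, percent.
#' @param date Optional date label for the row.
#' @return One-row data frame: `date`, `hst_hours`, `hrt_hours`,
#'   `hours_s_gt15`, `hours_hr_gt90`, `hours_hsi_gt30`, `valid_hours`.
#' @export
daily_budget <- function(utci, s, hr, hsi, date = NA) {
  n <- length(utci)
  if (length(s) != n || length(hr) != n || length(hsi) != n) {
    stop_bioheat("hourly series must be aligned (equal lengths)",
                 class = "bioheat_input_error")
  }
  data.frame(
    date = date,
    hst_hours = sum(utci > 26),
    hrt_hours = sum(utci < 18),
    hours_s_gt15 = sum(s > 15),
    hours_hr_gt90 = sum(hr > 90),
    hours_hsi_gt30 = sum(hsi > 30),
    valid_hours = n
  )
}
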