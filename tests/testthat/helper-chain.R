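# Shared fixture builders: run the radiation -> UTCI chain on an
# observation table, and write small weather files for the I/O tests.

run_chain <- function(obs, latitude = 52.2, longitude = 21.0) {
  sol <- solar_position(latitude, longitude, obs$timestamp)
  kglob <- global_radiation(sol$elevation, obs$cloud)
  tmrt <- mean_radiant_temp(obs$ta, obs$vp, obs$cloud, kglob, sol$elevation)
  utci <- compute_utci(obs$ta, tmrt, obs$v10, obs$vp)
  cbind(obs, elevation = sol$elevation, kglob = kglob, tmrt = tmrt, utci)
}

# a small hand-built hourly table: one station, n complete hours from 00 UTC
make_obs <- function(n = 24, ta = 20, vp = 15, v10 = 3, cloud = 0.5,
                     station = "S1", start = "2019-06-01") {
  data.frame(
    station_id = station,
    timestamp = as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * 3600,
    ta = rep_len(ta, n), vp = rep_len(vp, n),
    v10 = rep_len(v10, n), cloud = rep_len(cloud, n),
    stringsAsFactors = FALSE
  )
}

write_weather_file <- function(obs, dialect = io_dialect()) {
  path <- tempfile(fileext = ".csv")
  write_hourly(obs, path, dialect)
  path
}

# independent Magnus saturation pressure (hPa) for invariant checks
saturation_vp_for_test <- function(ta) {
  6.105 * exp(17.27 * ta / (237.7 + ta))
}
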