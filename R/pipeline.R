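# End-to-end orchestration: weather -> radiation -> UTCI -> indicators ->
# strain -> mortality -> report, under one declarative config with
# reproducibility metadata.

#' Build a run configuration
#'
#' Collects every knob of an end-to-end run in one structure: the synthetic
#' scenarios (or input paths), the reference period, the category basis for
#' calling a day's thermal stress, all thresholds, and the radiation
#' constants. Every constant is echoed into the run metadata so a run is
#' fully reconstructable from its output directory.
#'
#' @param analysis_year Year under analysis.
#' @param reference_years Reference period (vector of years).
#' @param analysis_scenario [weather_scenario()] for the analysis year
#'   (default: a hot June with two embedded heat waves).
#' @param reference_scenario [weather_scenario()] template for reference
#'   years (default: an ordinary June, clearly cooler, with two short
#'   two-day hot spells that yield about one strong-heat day per June on
#'   average).
#' @param mortality [mortality_scenario()] shared by all years.
#' @param weather_path Optional path to an hourly weather CSV; when given
#'   it replaces the analysis-year synthetic scenario.
#' @param category_basis `"utci_12"` (midday value, the default: midday
#'   represents the most heat-stressed hours of the day) or `"utci_max"`;
#'   selects the daily UTCI value whose category labels the day.
#' @param midday_hour Hour (UTC) of the midday record.
#' @param min_hours Completeness threshold for a valid day.
#' @param radiation [radiation_constants()].
#' @param thresholds Named list of strain thresholds (defaults: S 15 W/m2,
#'   HR 90 beats/min, HSI 30 percent, HST above 26 degC, HRT below 18
#'   degC, heat-wave tmax 30 degC over at least 3 days).
#' @param seed Master seed; all per-year and mortality streams derive from
#'   it.
#' @param out_dir Output directory (`NULL` to skip writing files).
#' @return List of class `run_config`.
#' @export
run_config <- function(analysis_year = 2019,
                       reference_years = 2010:2018,
                       analysis_scenario = weather_scenario(),
                       reference_scenario = weather_scenario(
                         base_mean_ta = 15,
                         heat_wave_windows = list(c(8, 2, 11),
                                                  c(20, 2, 11))
                       ),
                       mortality = mortality_scenario(),
                       weather_path = NULL,
                       category_basis = c("utci_12", "utci_max"),
                       midday_hour = 12L,
                       min_hours = 18L,
                       radiation = radiation_constants(),
                       thresholds = list(storage = 15, heart_rate = 90,
                                         sultriness = 30, hst = 26,
                                         hrt = 18, heat_wave_tmax = 30,
                                         heat_wave_days = 3L),
                       seed = 1L,
                       out_dir = NULL) {
  category_basis <- match.arg(category_basis)
  if (length(reference_years) < 1) {
    stop_bioheat("'reference_years' must be non-empty",
                 class = "bioheat_input_error")
  }
  if (any(unlist(thresholds) <= 0)) {
    stop_bioheat("thresholds must be positive", class = "bioheat_input_error")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Reads a structured config file whose top-level keys mirror the
#' [run_config()] arguments (`analysis_scenario`, `reference_scenario` and
#' `mortality` given as nested key-value blocks).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("analysis_year", "reference_years", "category_basis",
               "midday_hour", "min_hours", "seed", "out_dir",
               "weather_path")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  fix_waves <- function(sc) {
    if (!is.null(sc$heat_wave_windows)) {
      sc$heat_wave_windows <- lapply(sc$heat_wave_windows, unlist)
    }
    if (!is.null(sc$start_date)) sc$start_date <- as.Date(sc$start_date)
    sc
  }
  if (!is.null(y$analysis_scenario)) {
    args$analysis_scenario <-
      do.call(weather_scenario, fix_waves(y$analysis_scenario))
  }
  if (!is.null(y$reference_scenario)) {
    args$reference_scenario <-
      do.call(weather_scenario, fix_waves(y$reference_scenario))
  }
  if (!is.null(y$mortality)) {
    args$mortality <- do.call(mortality_scenario, y$mortality)
  }
  if (!is.null(y$radiation)) {
    args$radiation <- do.call(radiation_constants, y$radiation)
  }
  if (!is.null(y$thresholds)) args$thresholds <- y$thresholds
  do.call(run_config, args)
}

# derived deterministic sub-seed per year, kept below 2^31
year_seed <- function(seed, year, salt = 0L) {
  (as.integer(seed) %% 10000L) * 100000L + (year %% 1000L) * 10L + salt
}

#' UTCI chain from raw observations
#'
#' Convenience wrapper running the whole hourly chain on an observation
#' table: solar position, cloud-attenuated global radiation, mean radiant
#' temperature, then UTCI with its stress category.
#'
#' @param obs Hourly observations (see [read_hourly()] or
#'   [generate_weather()]).
#' @param latitude,longitude Site coordinates, degrees.
#' @param constants Radiation constants, see [radiation_constants()].
#' @return `obs` with columns `elevation`, `kglob`, `tmrt`, `utci`,
#'   `category`, `clamped` appended.
#' @export
utci_from_observations <- function(obs, latitude, longitude,
                                   constants = radiation_constants()) {
  sol <- solar_position(latitude, longitude, obs$timestamp)
  kglob <- global_radiation(sol$elevation, obs$cloud, constants)
  tmrt <- mean_radiant_temp(obs$ta, obs$vp, obs$cloud, kglob,
                            sol$elevation, constants)
  utci <- compute_utci(obs$ta, tmrt, obs$v10, obs$vp)
  cbind(obs, elevation = sol$elevation, kglob = kglob, tmrt = tmrt, utci)
}

# hourly chain for one observation table: radiation -> tmrt -> utci
hourly_chain <- function(obs, scenario, config) {
  utci_from_observations(obs, scenario$latitude, scenario$longitude,
                         config$radiation)
}

# single-year pass: weather -> hourly chain -> daily -> indicators, waves,
# strain budgets, deaths
run_year <- function(year, scenario, config, weather = NULL) {
  sc <- scenario
  sc$seed <- year_seed(config$seed, year)
  sc$start_date <- as.Date(sprintf("%04d-%02d-%02d", year,
                                   as.POSIXlt(scenario$start_date)$mon + 1,
                                   1))
  obs <- weather %||% generate_weather(sc)
  hourly <- hourly_chain(obs, sc, config)
  daily <- aggregate_daily(obs, hourly$utci, config$midday_hour,
                           config$min_hours)

  basis <- if (config$category_basis == "utci_12") daily$utci_12 else
    daily$utci_max
  categories <- classify_stress(ifelse(is.na(basis), -99, basis))
  categories[is.na(basis)] <- NA

  indicators <- count_threshold_days(daily)
  waves <- detect_heat_waves(daily$date, daily$tmax,
                             config$thresholds$heat_wave_tmax,
                             config$thresholds$heat_wave_days)

  person <- person_config()
  fluxes <- heat_balance(obs, hourly$tmrt, person)
  hr <- heart_rate(person$metabolic_rate, obs$ta, obs$vp)
  hsi <- sultriness_index(fluxes, wind_at_height(obs$v10), obs$vp,
                          person$k)
  date <- as.Date(obs$timestamp, tz = "UTC")
  budgets <- do.call(rbind, lapply(split(seq_len(nrow(obs)), date),
    function(i) daily_budget(hourly$utci[i], fluxes$S[i], hr[i], hsi[i],
                             date[i[1]])))
  rownames(budgets) <- NULL

  msc <- config$mortality
  msc$seed <- year_seed(config$seed, year, salt = 7L)
  deaths <- generate_mortality(categories, msc)

  stress_days <- sum(categories %in% c("SHS", "VSHS"), na.rm = TRUE)
  shs <- sum(categories == "SHS", na.rm = TRUE)
  vshs <- sum(categories == "VSHS", na.rm = TRUE)
  pop_rate <- config$mortality$population / 1e5
  list(
    year = year, hourly = hourly, daily = daily, categories = categories,
    indicators = indicators, waves = waves, budgets = budgets,
    deaths = deaths,
    aggregate = data.frame(
      year = year,
      deaths = sum(deaths),
      utci_12_mean = monthly_mean(daily$utci_12)$mean,
      stress_days = stress_days,
      shrm = shrm(pop_rate, shs, vshs)
    )
  )
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) hourly weather for the analysis year and every
#' reference year, runs the radiation/UTCI chain, aggregates daily
#' summaries, computes heat indicators, heat waves and strain budgets,
#' simulates daily mortality, and assembles the yearly report table
#' (TMrel, SHRMrel, monthly midday UTCI, strong-heat days) together with
#' the analysis-year anomalies against the reference period. With an
#' `out_dir` set, all stage tables are written as delimited text plus a
#' `metadata.json` recording the config (hash, seed, every constant);
#' identical config and seed reproduce identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list: `report` (yearly table, reference-mean row
#'   appended), `anomalies` (midday-UTCI and stress-day anomalies of the
#'   analysis year), `years` (per-year stage outputs), `heat_effect`
#'   (estimated relative risk on strong-heat days, when both strata occur
#'   in the analysis year), `metadata`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  weather <- NULL
  if (!is.null(config$weather_path)) {
    weather <- read_hourly(config$weather_path)
  }
  years <- list()
  for (y in config$reference_years) {
    years[[as.character(y)]] <- run_year(y, config$reference_scenario,
                                         config)
  }
  ana <- run_year(config$analysis_year, config$analysis_scenario, config,
                  weather = weather)
  years[[as.character(config$analysis_year)]] <- ana

  agg <- do.call(rbind, lapply(years, `[[`, "aggregate"))
  report <- table1_report(agg, config$reference_years)

  ref_rows <- agg$year %in% config$reference_years
  anomalies <- list(
    utci_12_mean = anomaly(agg$utci_12_mean[agg$year == config$analysis_year],
                           agg$utci_12_mean[ref_rows]),
    stress_days = anomaly(agg$stress_days[agg$year == config$analysis_year],
                          agg$stress_days[ref_rows])
  )

  heat_effect <- NULL
  n_stress <- sum(ana$categories %in% c("SHS", "VSHS"), na.rm = TRUE)
  n_other <- sum(!is.na(ana$categories)) - n_stress
  if (n_stress > 0 && n_other > 0) {
    heat_effect <- estimate_heat_effect(
      ana$deaths, ana$categories,
      seed = year_seed(config$seed, config$analysis_year, salt = 9L)
    )
  }

  metadata <- list(
    package_version = as.character(utils::packageVersion("bioheat")),
    seed = config$seed,
    config_hash = config_hash(config),
    category_basis = config$category_basis,
    midday_hour = config$midday_hour,
    min_hours = config$min_hours,
    thresholds = config$thresholds,
    radiation = config$radiation
  )
  out <- list(report = report, anomalies = anomalies, years = years,
              heat_effect = heat_effect, metadata = metadata)
  if (!is.null(config$out_dir)) {
    write_bundle(out, ana, config)
  }
  invisible(out)
}

# stable hash of the config: md5 of its canonical JSON serialisation;
# the output location is not part of a run's scientific identity
config_hash <- function(config) {
  config <- unclass(config)
  config$out_dir <- NULL
  plain <- rapply(config, function(x) {
    if (inherits(x, "Date") || inherits(x, "POSIXct")) format(x) else x
  }, how = "replace")
  json <- jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

write_bundle <- function(out, ana, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  utils::write.table(out$report, p("report.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(ana$daily, p("daily_summary.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(ana$budgets, p("strain_budgets.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(ana$waves, p("heat_waves.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(ana$indicators, p("indicators.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(out$metadata, p("metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

#' Yearly report table
#'
#' Assembles the yearly summary table: deaths, TMrel against the
#' reference-period mean, SHRM and SHRMrel, monthly midday UTCI, number of
#' strong-heat days, and (when pollutant columns `o3` / `pm25` are
#' present) their means and percent-of-reference values. A reference-mean
#' row is appended; its relative columns are 100 by construction. Years
#' with missing death counts are excluded from the reference mean, never
#' imputed, and keep a blank TMrel cell.
#'
#' @param aggregates Data frame with one row per year: `year`, `deaths`,
#'   `utci_12_mean`, `stress_days`, `shrm`, optionally `o3`, `pm25`.
#' @param reference_years Years forming the reference period.
#' @return The table with `tmrel`, `shrmrel` (and pollutant relatives)
#'   added and a summary row (`year = "reference_mean"`) appended.
#' @export
table1_report <- function(aggregates, reference_years) {
  agg <- aggregates
  ref <- agg[agg$year %in% reference_years, , drop = FALSE]
  if (nrow(ref) == 0) {
    stop_bioheat("no reference-year rows in 'aggregates'",
                 class = "bioheat_input_error")
  }
  tmavg <- monthly_mean(ref$deaths)$mean
  agg$tmrel <- tm_rel(agg$deaths, tmavg)
  shrm_ref <- mean(ref$shrm, na.rm = TRUE)
  agg$shrmrel <- if (shrm_ref > 0) shrm_rel(agg$shrm, shrm_ref) else
    NA_real_
  rel_cols <- character()
  for (pol in c("o3", "pm25")) {
    if (pol %in% names(agg)) {
      pref <- monthly_mean(ref[[pol]])$mean
      agg[[paste0(pol, "_rel")]] <- 100 * agg[[pol]] / pref
      rel_cols <- c(rel_cols, pol, paste0(pol, "_rel"))
    }
  }
  ref_row <- agg[1, , drop = FALSE]
  ref_row$year <- NA
  ref_row$deaths <- tmavg
  ref_row$utci_12_mean <- mean(ref$utci_12_mean, na.rm = TRUE)
  ref_row$stress_days <- mean(ref$stress_days, na.rm = TRUE)
  ref_row$shrm <- shrm_ref
  ref_row$tmrel <- 100
  ref_row$shrmrel <- if (shrm_ref > 0) 100 else NA_real_
  for (pol in c("o3", "pm25")) {
    if (pol %in% names(agg)) {
      ref_row[[pol]] <- monthly_mean(ref[[pol]])$mean
      ref_row[[paste0(pol, "_rel")]] <- 100
    }
  }
  out <- rbind(agg, ref_row)
  out$period <- c(as.character(agg$year), "reference_mean")
  rownames(out) <- NULL
  out[c("period", setdiff(names(out), c("period", "year")))]
}
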