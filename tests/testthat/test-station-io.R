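# Reading, validation and daily aggregation of station weather tables.

test_that("write-then-read round trip is the identity", {
  obs <- make_obs(48, ta = sin(1:48) * 5 + 20, vp = 10 + (1:48) %% 7,
                  v10 = 1 + (1:48) %% 5 / 2, cloud = ((1:48) %% 9) / 8)
  for (units in c("fraction", "oktas")) {
    dialect <- io_dialect(cloud_units = units)
    back <- read_hourly(write_weather_file(obs, dialect), dialect)
    expect_equal(back$timestamp, obs$timestamp)
    expect_equal(back$ta, obs$ta)
    expect_equal(back$vp, obs$vp)
    expect_equal(back$v10, obs$v10)
    expect_equal(back$cloud, obs$cloud)
  }
})

test_that("oktas are converted to a fraction on read", {
  obs <- make_obs(2)
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "station_id,timestamp,ta,vp,v10,cloud",
    "S1,2019-06-01T00:00:00+00:00,20,15,3,4",
    "S1,2019-06-01T01:00:00+00:00,20,15,3,8"
  ), path)
  got <- read_hourly(path, io_dialect(cloud_units = "oktas"))
  expect_equal(got$cloud, c(0.5, 1))
})

test_that("invalid rows are rejected individually with diagnostics", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "station_id,timestamp,ta,vp,v10,cloud",
    "S1,2019-06-01T00:00:00+00:00,20,15,3,4",
    "S1,2019-06-01T01:00:00+00:00,20,15,3,9",   # 9 oktas: invalid
    "S1,not-a-time,20,15,3,4",
    "S1,2019-06-01T03:00:00+00:00,20,-1,3,4"    # negative vp
  ), path)
  expect_warning(
    got <- read_hourly(path, io_dialect(cloud_units = "oktas")),
    "rejected 3"
  )
  expect_equal(nrow(got), 1)
  rej <- attr(got, "rejected")
  expect_setequal(rej$line, c(3L, 4L, 5L))
  expect_true(any(grepl("oktas", rej$reason)))
  expect_true(any(grepl("timestamp", rej$reason)))
})

test_that("missing columns and duplicate station-hours are errors", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("station_id,timestamp,ta", "S1,2019-06-01T00:00:00Z,20"),
             path)
  expect_error(read_hourly(path), class = "bioheat_config_error")

  dup <- make_obs(2)
  dup$timestamp[2] <- dup$timestamp[1]
  expect_error(read_hourly(write_weather_file(dup)),
               class = "bioheat_io_error")
})

test_that("timestamps with offsets are normalised to UTC", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "station_id,timestamp,ta,vp,v10,cloud",
    "S1,2019-06-01T14:00:00+02:00,20,15,3,0.5",
    "S1,2019-06-01T13:00:00Z,19,15,3,0.5"
  ), path)
  got <- read_hourly(path)
  expect_equal(format(got$timestamp, "%H", tz = "UTC"), c("12", "13"))
})

test_that("daily aggregation of a constant series returns the constant", {
  obs <- make_obs(24, ta = 20)
  d <- aggregate_daily(obs, utci = rep(22, 24))
  expect_equal(d$tmax, 20)
  expect_equal(d$tmin, 20)
  expect_equal(d$tavg, 20)
  expect_equal(d$utci_avg, 22)
  expect_equal(d$utci_max, 22)
  expect_true(d$complete)
})

test_that("24-h and midday statistics follow their definitions", {
  obs <- make_obs(24, ta = c(rep(18, 12), rep(30, 12)))
  d <- aggregate_daily(obs, utci = c(rep(10, 12), rep(28, 12)))
  expect_equal(d$tmax, 30)
  expect_equal(d$tmin, 18)
  expect_equal(d$tavg, 24)
  expect_equal(d$ta_12, 30)
  expect_equal(d$utci_12, 28)
  expect_equal(d$utci_avg, 19)
  expect_true(d$utci_max >= d$utci_avg)
})

test_that("aggregation is permutation-invariant within a day", {
  obs <- make_obs(24, ta = rnorm(24, 20, 4), vp = runif(24, 8, 20))
  u <- rnorm(24, 22, 5)
  perm <- sample(24)
  d1 <- aggregate_daily(obs, u)
  d2 <- aggregate_daily(obs[perm, ], u[perm])
  expect_equal(d1, d2)
})

test_that("incomplete days are flagged, missing midday gives NA not a guess", {
  obs <- make_obs(3)  # hours 00-02 only
  d <- aggregate_daily(obs, utci = rep(20, 3), min_hours = 18)
  expect_false(d$complete)
  expect_equal(d$n_hours, 3)
  expect_true(is.na(d$utci_12))
  expect_true(is.na(d$ta_12))
})

test_that("mortality tables read with missing counts preserved as NA", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "city_id,year,month,deaths,population",
    "WAW,2010,6,1500,1700000",
    "WAW,2011,6,NA,1700000"
  ), path)
  m <- read_mortality(path)
  expect_equal(m$deaths, c(1500, NA))
  expect_equal(m$population, c(1700000, 1700000))
})
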