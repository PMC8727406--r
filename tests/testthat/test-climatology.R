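# Threshold-day counts, heat-wave detection, anomalies, monthly means.

test_that("threshold day and night counts use strict inequalities", {
  d <- data.frame(tmax = c(24.9, 25.1, 31, 36),
                  tmin = c(18.5, 20.5, 17.0, 15))
  got <- count_threshold_days(d)
  expect_equal(got$hot_days, 3)
  expect_equal(got$very_hot_days, 2)
  expect_equal(got$extremely_hot_days, 1)
  expect_equal(got$warm_nights, 2)
  expect_equal(got$tropical_nights, 1)

  empty <- count_threshold_days(d[0, ])
  expect_equal(empty$hot_days, 0)
  expect_equal(empty$n_days, 0)
})

test_that("incomplete days are excluded from counts and reported", {
  d <- data.frame(tmax = c(31, 31, 31), tmin = c(19, 19, 19),
                  complete = c(TRUE, FALSE, TRUE))
  got <- count_threshold_days(d)
  expect_equal(got$very_hot_days, 2)
  expect_equal(got$n_excluded, 1)
})

test_that("counts nest: extremely hot within very hot within hot", {
  set.seed(42)
  for (i in 1:50) {
    d <- data.frame(tmax = runif(30, 20, 40), tmin = runif(30, 10, 25))
    got <- count_threshold_days(d)
    expect_lte(got$extremely_hot_days, got$very_hot_days)
    expect_lte(got$very_hot_days, got$hot_days)
    expect_lte(got$tropical_nights, got$warm_nights)
  }
})

test_that("heat waves are maximal runs of at least three days above 30", {
  dates <- seq(as.Date("2019-06-01"), by = "day", length.out = 6)
  got <- detect_heat_waves(dates, c(31, 32, 33, 29, 31, 31))
  expect_equal(nrow(got), 1)
  expect_equal(got$start_date, dates[1])
  expect_equal(got$length_days, 3L)

  # boundary is strict: 30.0 does not count
  expect_equal(nrow(detect_heat_waves(dates[1:3], c(30, 30, 30))), 0)

  # a single maximal run spanning the whole month
  d30 <- seq(as.Date("2019-06-01"), by = "day", length.out = 30)
  got30 <- detect_heat_waves(d30, rep(31, 30))
  expect_equal(got30$length_days, 30L)

  # two runs separated by one cool day stay distinct
  got2 <- detect_heat_waves(dates, c(31, 31, 31, 29, 31, 31), min_length = 2)
  expect_equal(nrow(got2), 2)
})

test_that("a gap in the date series is an error", {
  dates <- as.Date(c("2019-06-01", "2019-06-02", "2019-06-04"))
  expect_error(detect_heat_waves(dates, c(31, 31, 31)),
               class = "bioheat_input_error")
})

test_that("heat-wave detection equals brute-force window enumeration", {
  brute <- function(tmax, threshold = 30, min_length = 3) {
    hot <- tmax > threshold
    waves <- list()
    i <- 1
    while (i <= length(hot)) {
      if (hot[i]) {
        j <- i
        while (j < length(hot) && hot[j + 1]) j <- j + 1
        if (j - i + 1 >= min_length) {
          waves[[length(waves) + 1]] <- c(i, j - i + 1)
        }
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
    waves
  }
  set.seed(7)
  dates <- seq(as.Date("2019-06-01"), by = "day", length.out = 30)
  for (rep in 1:200) {
    tmax <- round(runif(30, 27, 33), 1)
    got <- detect_heat_waves(dates, tmax)
    want <- brute(tmax)
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      expect_equal(as.integer(got$start_date - dates[1]) + 1,
                   vapply(want, `[`, numeric(1), 1))
      expect_equal(got$length_days, vapply(want, `[`, numeric(1), 2))
    }
  }
})

test_that("anomalies decompose into absolute and SD-scaled parts", {
  ref <- c(18, 20, 22)  # mean 20, sd 2
  got <- anomaly(26.8, ref)
  expect_equal(got$absolute, 6.8)
  expect_equal(got$relative_sd, 3.4)
  expect_equal(got$ref_n, 3)

  same <- anomaly(20, ref)
  expect_equal(same$absolute, 0)
  expect_equal(same$relative_sd, 0)

  const <- anomaly(25, c(20, 20, 20))
  expect_equal(const$absolute, 5)
  expect_true(is.na(const$relative_sd))
})

test_that("anomaly is location-equivariant", {
  ref <- rnorm(10, 20, 3)
  a <- anomaly(25, ref)
  b <- anomaly(25 + 7, ref + 7)
  expect_equal(a$absolute, b$absolute)
  expect_equal(a$relative_sd, b$relative_sd)
})

test_that("anomaly uses the sample (n-1) standard deviation", {
  ref <- c(1, 2, 3, 4)
  expect_equal(anomaly(5, ref)$ref_sd, sd(ref))
})

test_that("monthly mean filters missing sentinels and reports the count", {
  got <- monthly_mean(c(61.3, 67.9, 65.1))
  expect_equal(got$mean, 64.76667, tolerance = 1e-6)
  expect_equal(got$n, 3)
  expect_equal(monthly_mean(5)$mean, 5)
  withna <- monthly_mean(c(10, NA, 20))
  expect_equal(withna$mean, 15)
  expect_equal(withna$n, 2)
  expect_error(monthly_mean(c(NA_real_, NA_real_)),
               class = "bioheat_input_error")
})
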