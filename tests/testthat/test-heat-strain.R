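# Heat balance, heart rate, sultriness and daily hour budgets.

test_that("heart rate reproduces the regression's worked values", {
  expect_equal(heart_rate(135, 30, 20), 97.5)
  expect_equal(heart_rate(135, 0, 0), 46.7)
  # just over the 90 beats/min warning level
  expect_equal(heart_rate(135, 25, 18.2), 90.053)
  expect_gt(heart_rate(135, 25, 18.2), 90)
})

test_that("heart rate is exactly linear in ta and vp", {
  ta <- runif(20, 0, 35); vp <- runif(20, 0, 30)
  expect_equal(heart_rate(135, ta + 1, vp) - heart_rate(135, ta, vp),
               rep(1.25, 20))
  expect_equal(heart_rate(135, ta, vp + 1) - heart_rate(135, ta, vp),
               rep(0.665, 20))
})

test_that("net heat storage conserves the component sum exactly", {
  w <- generate_weather(weather_scenario(seed = 13L))
  ch <- run_chain(w)
  fl <- heat_balance(w, ch$tmrt)
  expect_identical(fl$S, fl$M + fl$Q + fl$E + fl$C + fl$Res)
  expect_true(all(fl$E <= 0))
  expect_true(all(fl$Res <= 0))
  expect_true(all(abs(fl$E) <= pmax(fl$emax, 0) + 1e-12))
})

test_that("storage follows the balance through cooling, neutral and heat", {
  # cool conditions: no sweating demand, E = 0 and the storage is the raw
  # (negative) balance
  cool <- make_obs(1, ta = 18, vp = 10, v10 = 3)
  fl_cool <- heat_balance(cool, tmrt = 18)
  expect_lt(fl_cool$ereq, 0)
  expect_equal(fl_cool$E, 0)
  expect_equal(fl_cool$S, fl_cool$ereq)

  # warm conditions with sweating within capacity: the wettedness
  # efficiency identity S = Ereq^2 / (2 Emax) holds exactly, and the
  # storage vanishes continuously at the thermoneutral point Ereq = 0
  warm <- make_obs(1, ta = 30, vp = 20, v10 = 2)
  fl <- heat_balance(warm, tmrt = 35)
  expect_gt(fl$ereq, 0)
  expect_lt(fl$ereq, fl$emax)
  expect_equal(fl$S, fl$ereq^2 / (2 * fl$emax))

  # clear noon, hot, humid and calm: demand far exceeds what calm air can
  # absorb and storage passes the overheating threshold
  hot <- make_obs(1, ta = 33, vp = 22, v10 = 0.5, cloud = 0)
  noonch <- run_chain(make_obs(13, ta = 33, vp = 22, v10 = 0.5, cloud = 0))
  fl_hot <- heat_balance(hot, tmrt = noonch$tmrt[13])  # 12 UTC record
  expect_gt(fl_hot$S, 15)
  expect_true(fl_hot$overheating)
})

test_that("flux-set component sum identity holds for stated components", {
  s <- sum(c(135, 80, -120, -40, -10))
  expect_equal(s, 45)
  fl <- data.frame(M = 135, Q = 80, E = -120, C = -40, Res = -10)
  expect_equal(fl$M + fl$Q + fl$E + fl$C + fl$Res, 45)
})

test_that("sultriness index follows its ratio definition and caps", {
  # Emax = 7 * 1 * 0.6 * (56 - 16) = 168; HSI = 100 * 84 / 168 = 50
  expect_equal(sultriness_index(84, v12 = 1, vp = 16, k = 7), 50)
  expect_equal(sultriness_index(-10, v12 = 1, vp = 16, k = 7), 0)
  expect_equal(sultriness_index(50, v12 = 1, vp = 56, k = 7), 100)
  expect_equal(sultriness_index(50, v12 = 1, vp = 60, k = 7), 100)
  expect_equal(sultriness_index(400, v12 = 1, vp = 16, k = 7), 100)
})

test_that("sultriness falls with wind and rises with humidity when uncapped", {
  v <- seq(0.5, 4, 0.5)
  hsi_v <- sultriness_index(rep(60, length(v)), v, 16, 7)
  expect_true(all(diff(hsi_v) < 0))
  vp <- seq(10, 30, 2)
  hsi_vp <- sultriness_index(rep(60, length(vp)), 2, vp, 7)
  expect_true(all(diff(hsi_vp) > 0))
})

test_that("wind profile converts 10-m wind to 1.2 m with the log law", {
  expect_equal(wind_at_height(1), log(120) / log(1000))
  expect_equal(wind_at_height(3) / 3, wind_at_height(5) / 5)
})

test_that("daily budgets count strict threshold exceedances", {
  b <- daily_budget(rep(30, 24), rep(0, 24), rep(80, 24), rep(0, 24))
  expect_equal(b$hst_hours, 24)
  expect_equal(b$hrt_hours, 0)

  u <- c(rep(15, 8), rep(28, 10), rep(22, 6))
  b2 <- daily_budget(u, rep(0, 24), rep(0, 24), rep(0, 24))
  expect_equal(b2$hst_hours, 10)
  expect_equal(b2$hrt_hours, 8)

  # boundary values do not count
  b3 <- daily_budget(c(26, 18), c(15, 15), c(90, 90), c(30, 30))
  expect_equal(b3$hst_hours, 0)
  expect_equal(b3$hrt_hours, 0)
  expect_equal(b3$hours_s_gt15, 0)
  expect_equal(b3$hours_hr_gt90, 0)
  expect_equal(b3$hours_hsi_gt30, 0)

  expect_error(daily_budget(1:24, 1:23, 1:24, 1:24),
               class = "bioheat_input_error")
})

test_that("comfort band hours complement HST and HRT exactly", {
  set.seed(31)
  for (i in 1:50) {
    u <- runif(24, 10, 35)
    b <- daily_budget(u, rep(0, 24), rep(0, 24), rep(0, 24))
    comfort <- sum(u >= 18 & u <= 26)
    expect_equal(comfort, b$valid_hours - b$hst_hours - b$hrt_hours)
  }
})

test_that("person configuration selects the evaporation coefficient", {
  expect_equal(person_config(clothed = TRUE)$k, 7.0)
  expect_equal(person_config(clothed = FALSE)$k, 11.7)
  expect_error(person_config(metabolic_rate = 0),
               class = "bioheat_input_error")
})
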