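test_that("lunar day of year anchors to the bundled new-year table", {
  expect_equal(lunar_day_of_year(as.Date("2015-02-19")), 1L)
  expect_equal(lunar_day_of_year(as.Date("2015-03-05")), 15L)
  # a date before the year's new year anchors to the previous lunar year
  expect_equal(lunar_day_of_year(as.Date("2016-02-07")),
               as.integer(as.Date("2016-02-07") - as.Date("2015-02-19")) + 1L)
  expect_error(lunar_day_of_year(as.Date("1985-06-01")), "does not cover")
  short <- lunar_new_year_dates()[lunar_new_year_dates()$year >= 2015, ]
  expect_error(lunar_day_of_year(as.Date("2015-01-05"), short),
               "does not cover")
})

test_that("build_features produces calendar identities and flags bad met", {
  sp <- small_panel()
  unit <- sp$panel[sp$panel$city_id == "C01", ]
  f <- build_features(unit)
  i <- which(format(f$timestamp, "%Y-%m-%d %H", tz = "UTC") == "2016-01-01 00")
  expect_equal(f$day_of_year[i], 1L)
  expect_equal(f$hour_of_day[i], 0L)
  expect_equal(f$unix_trend[i], as.numeric(f$timestamp[i]))
  expect_true(all(f$day_of_week %in% 1:7))
  expect_true(all(f$hour_of_day %in% 0:23))
  expect_true(all(f$lunar_day_of_year >= 1 & f$lunar_day_of_year <= 385))
  # missing met flags the row
  unit2 <- unit
  unit2$blh[5] <- NA
  f2 <- build_features(unit2)
  expect_false(f2$met_ok[5])
  expect_true(f2$met_ok[6])
})

test_that("train_rf meets the deweathering performance contract", {
  sp <- small_panel()
  unit <- sp$panel[sp$panel$city_id == "C01", ]
  f <- build_features(unit)
  m <- train_rf(f, unit$pm25, rf_config(seed = 7))
  expect_gt(m$metrics$r, 0.7)
  expect_lt(abs(m$metrics$bias), 1)
  expect_equal(m$metrics$n_train + m$metrics$n_test, sum(f$met_ok))
  # seed determinism of the split and forest
  m2 <- train_rf(f, unit$pm25, rf_config(seed = 7))
  expect_identical(m$metrics, m2$metrics)
})

test_that("train_rf handles degenerate targets", {
  sp <- small_panel()
  unit <- sp$panel[sp$panel$city_id == "C02", ]
  f <- build_features(unit)
  expect_warning(m <- train_rf(f, rep(5, nrow(f)), rf_config(seed = 1)),
                 "r undefined")
  expect_equal(m$metrics$r, 0)
  pred <- predict(m$forest, f[1:10, c(synthaq:::TIME_VARS,
                                      synthaq:::MET_VARS)],
                  num.threads = 1)$predictions
  expect_equal(pred, rep(5, 10))
  expect_error(train_rf(f[1:100, ], unit$pm25[1:100], rf_config()),
               "valid rows")
})

test_that("forest recovers a smooth deterministic function of temperature", {
  sp <- small_panel()
  unit <- sp$panel[sp$panel$city_id == "C03", ]
  f <- build_features(unit)
  target <- 40 + 2 * unit$temp - 0.05 * unit$temp^2
  m <- train_rf(f, target, rf_config(seed = 3))
  expect_gt(m$metrics$r, 0.95)
})

test_that("deweathering a met-independent model returns its plain prediction", {
  sp <- small_panel()
  unit <- sp$panel[sp$panel$city_id == "C04", ]
  # a model that provably ignores meteorology: the met columns are constant,
  # so no tree can split on them and predictions depend on time only
  for (v in synthaq:::MET_VARS) unit[[v]] <- c(temp = 10, rh = 60, ws = 2,
                                               wd = 180, pressure = 1013,
                                               blh = 500, tcc = 0.5,
                                               ssr = 1e5, tp = 0)[[v]]
  f <- build_features(unit)
  target <- 30 + 4 * f$day_of_week
  cfg <- rf_config(n_resample = 25, seed = 5)
  m <- train_rf(f, target, cfg)
  at <- f$timestamp[seq(1, 2000, by = 40)]
  dw <- deweather(m, f, cfg, at = at, clip_negative = FALSE)
  plain <- predict(m$forest, f[match(at, f$timestamp),
                               c(synthaq:::TIME_VARS, synthaq:::MET_VARS)],
                   num.threads = 1)$predictions
  expect_lt(max(abs(dw$value - plain) / pmax(abs(plain), 1)), 0.001)

  # with informative meteorology the identity holds only approximately:
  # small impure leaves leave a residual met dependence
  unit2 <- sp$panel[sp$panel$city_id == "C04", ]
  f2 <- build_features(unit2)
  m2 <- train_rf(f2, 30 + 4 * f2$day_of_week, cfg)
  dw2 <- deweather(m2, f2, cfg, at = at)
  plain2 <- predict(m2$forest, f2[match(at, f2$timestamp),
                                  c(synthaq:::TIME_VARS, synthaq:::MET_VARS)],
                    num.threads = 1)$predictions
  expect_lt(max(abs(dw2$value - plain2) / pmax(abs(plain2), 1)), 0.05)
})

test_that("deweathered series tracks the generator's non-met components", {
  sp <- small_panel()
  unit <- sp$panel[sp$panel$city_id == "T01", ]
  f <- build_features(unit)
  cfg <- rf_config(n_resample = 25, seed = 13)
  m <- train_rf(f, unit$pm25, cfg)
  hod <- as.integer(format(f$timestamp, "%H", tz = "UTC"))
  at <- f$timestamp[hod %% 6 == 0]
  dw <- deweather(m, f, cfg, at = at)
  tr <- sp$truth[sp$truth$pollutant == "pm25" & sp$truth$city_id == "T01", ]
  nonmet <- (tr$trend + tr$seasonal + tr$heating)[match(at, tr$timestamp)]
  # compare daily means so hourly noise averages out
  d <- as.Date(format(at, tz = "UTC"))
  dw_d <- tapply(dw$value, d, mean)
  tr_d <- tapply(nonmet, d, mean)
  rmse <- sqrt(mean((dw_d - tr_d)^2))
  expect_lt(rmse, 0.35 * sd(tr_d))
  # and correlates strongly with the emission + heating signal
  expect_gt(cor(dw_d, tr_d), 0.9)
})

test_that("deweathered full-period mean stays within 2% of the observed mean", {
  sp <- small_panel()
  unit <- sp$panel[sp$panel$city_id == "C05", ]
  f <- build_features(unit)
  cfg <- rf_config(n_resample = 25, seed = 17)
  m <- train_rf(f, unit$pm25, cfg)
  at <- f$timestamp[seq(1, nrow(f), by = 7)]  # even subsample for speed
  dw <- deweather(m, f, cfg, at = at)
  obs_mean <- mean(unit$pm25[match(at, unit$timestamp)])
  expect_lt(abs(mean(dw$value) - obs_mean) / obs_mean, 0.02)
  # seed determinism of the draws
  dw2 <- deweather(m, f, cfg, at = at)
  expect_identical(dw$value, dw2$value)
  # zero draws is refused
  expect_error(deweather(m, f, rf_config(n_resample = 0), at = at),
               "n_resample")
})

test_that("resampling noise shrinks roughly as one over the square root of draws", {
  sp <- small_panel()
  unit <- sp$panel[sp$panel$city_id == "C06", ]
  f <- build_features(unit)
  m <- train_rf(f, unit$pm25, rf_config(seed = 19))
  at <- f$timestamp[seq(1, 4000, by = 25)]
  ref <- deweather(m, f, rf_config(n_resample = 600, seed = 100), at = at)
  a <- deweather(m, f, rf_config(n_resample = 12, seed = 23), at = at)
  b <- deweather(m, f, rf_config(n_resample = 192, seed = 29), at = at)
  err_a <- mean(abs(a$value - ref$value))
  err_b <- mean(abs(b$value - ref$value))
  ratio <- err_a / err_b   # expected about sqrt(192/12) = 4
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})

test_that("weather effect is the aligned difference and rejects misalignment", {
  obs <- data.frame(timestamp = as.POSIXct("2020-01-01", tz = "UTC") +
                      3600 * 0:3, value = c(60, 50, NA, 40))
  dw <- structure(data.frame(timestamp = obs$timestamp,
                             value = c(50, 50, 10, 45)),
                  class = c("deweathered_series", "data.frame"))
  we <- weather_effect(obs, dw)
  expect_equal(we$value, c(10, 0, NA, -5))
  dw_bad <- dw[c(2, 1, 3, 4), ]
  expect_error(weather_effect(obs, dw_bad), "not aligned")
})

test_that("heating periods show no systematic weather-effect enhancement", {
  # the generator's met driver is (near) season-balanced after deweathering
  # with seasonal-window resampling: observed - deweathered should have
  # similar means in and out of heating periods relative to its spread
  sp <- small_panel()
  unit <- sp$panel[sp$panel$city_id == "T02", ]
  f <- build_features(unit)
  cfg <- rf_config(n_resample = 25, seed = 37)
  m <- train_rf(f, unit$pm25, cfg)
  hod <- as.integer(format(f$timestamp, "%H", tz = "UTC"))
  at <- f$timestamp[hod %% 6 == 0]
  dw <- deweather(m, f, cfg, at = at)
  obs <- unit$pm25[match(at, unit$timestamp)]
  we <- obs - dw$value
  d <- as.Date(format(at, tz = "UTC"))
  heat <- rep(FALSE, length(d))
  for (L in sp$config$heating_years) {
    heat <- heat | (d >= as.Date(sprintf("%d-11-08", L)) &
                      d <= as.Date(sprintf("%d-04-30", L + 1)))
  }
  gap <- abs(mean(we[heat]) - mean(we[!heat]))
  expect_lt(gap, 0.25 * sd(we))
})
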