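test_that("panel_config validates its invariants", {
  expect_error(panel_config(n_control_cities = 1), "n_control_cities")
  expect_error(panel_config(start_date = "2016-05-01",
                            end_date = "2016-01-01"), "precede")
  expect_error(panel_config(heating_effect = c(pm25 = -1)), ">= 0")
  expect_error(panel_config(alternative_fraction = 1.2), "alternative_fraction")
  expect_error(panel_config(populations = c(1, 2)), "one entry per city")
  # < 2 complete heating years refused when ASCM is requested
  expect_error(panel_config(start_date = "2015-05-01",
                            end_date = "2016-04-30"), "heating year")
  cfg <- panel_config(start_date = "2015-05-01", end_date = "2016-04-30",
                      require_ascm_years = FALSE)
  expect_identical(cfg$heating_years, 2015L)
})

test_that("components sum exactly to the observed value at every hour", {
  sp <- small_panel()
  tr <- sp$truth
  recon <- tr$trend + tr$seasonal + tr$met + tr$noise + tr$heating
  expect_lt(max(abs(recon - tr$observed)), 1e-9)
  # observed concentrations strictly positive
  for (p in c("pm25", "so2", "no2", "co", "o3")) {
    expect_gt(min(sp$panel[[p]]), 0)
  }
})

test_that("identical config and seed reproduce bit-identical panels", {
  cfg <- panel_config(n_control_cities = 2, n_treated_cities = 1,
                      n_alternative_cities = 0, seed = 9)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth, b$truth)
})

test_that("with all effects off, cities differ only by small persistent offsets", {
  cfg <- panel_config(n_control_cities = 2, n_treated_cities = 1,
                      n_alternative_cities = 0, seed = 5,
                      noise_sd = 0, met_effect_scale = 0, trend_slope = 0,
                      heating_effect = c(pm25 = 0, so2 = 0, no2 = 0,
                                         co = 0, o3 = 0))
  sp <- generate_panel(cfg)
  tr <- sp$truth[sp$truth$pollutant == "pm25", ]
  expect_true(all(tr$met == 0))
  expect_true(all(tr$noise == 0))
  expect_true(all(tr$heating == 0))
  # within a city the series is a deterministic seasonal/diel function:
  # same (doy, dow, hod, lunar doy) in different years gives the same value
  one <- tr[tr$city_id == "C01", ]
  key <- format(one$timestamp, "%m-%d %H", tz = "UTC")
  rep1 <- one$observed[key == "06-15 12"]
  expect_gt(length(rep1), 1)
  # trend off: only day-of-week and lunar-day differences remain (bounded by
  # twice the weekly amplitude)
  expect_lt(diff(range(rep1)), 4.5)
  # treated and control share the same seasonal shape up to the city scale
  c1 <- tr$observed[tr$city_id == "C01"]
  t1 <- tr$observed[tr$city_id == "T01"]
  expect_gt(cor(c1, t1), 0.99)
})

test_that("treated-control contrast over heating hours recovers the injected step", {
  sp <- small_panel()  # pm25 step = 10
  panel <- sp$panel
  d <- as.Date(format(panel$timestamp, tz = "UTC"))
  heat <- rep(FALSE, nrow(panel))
  for (L in sp$config$heating_years) {
    heat <- heat | (d >= as.Date(sprintf("%d-11-08", L)) &
                      d <= as.Date(sprintf("%d-04-30", L + 1)))
  }
  trt <- panel$city_id %in% sp$groups$city_id[sp$groups$role == "treated"]
  ctl <- panel$city_id %in% sp$groups$city_id[sp$groups$role == "control"]
  # difference-in-differences removes persistent city-level offsets that a
  # raw group contrast would keep (cities differ in baseline by design)
  did <- (mean(panel$pm25[heat & trt]) - mean(panel$pm25[heat & ctl])) -
    (mean(panel$pm25[!heat & trt]) - mean(panel$pm25[!heat & ctl]))
  expect_lt(abs(did - 10), 2.5)  # few-city Monte-Carlo tolerance
  # the decomposition's observed-minus-heating contrast is exact in
  # expectation: removing the recorded heating component must kill the gap
  tr <- sp$truth[sp$truth$pollutant == "pm25", ]
  base <- tr$observed - tr$heating
  trt_t <- tr$city_id %in% sp$groups$city_id[sp$groups$role == "treated"]
  dt <- as.Date(format(tr$timestamp, tz = "UTC"))
  heat_t <- rep(FALSE, nrow(tr))
  for (L in sp$config$heating_years) {
    heat_t <- heat_t | (dt >= as.Date(sprintf("%d-11-08", L)) &
                          dt <= as.Date(sprintf("%d-04-30", L + 1)))
  }
  gap_heating <- mean(tr$observed[heat_t & trt_t]) -
    mean(base[heat_t & trt_t])
  expect_equal(gap_heating, 10, tolerance = 1e-9)
  # ground-truth heating component is exactly the step for treated cities
  expect_equal(sort(unique(tr$heating[tr$city_id == "T01"])), c(0, 10))
  # alternative city gets alternative_fraction * step
  expect_equal(sort(unique(tr$heating[tr$city_id == "A01"])),
               c(0, 10 * sp$config$alternative_fraction))
})

test_that("increasing the heating effect raises treated heating means, controls unchanged", {
  base <- list(n_control_cities = 2, n_treated_cities = 1,
               n_alternative_cities = 0, seed = 21)
  eff <- c(5, 10, 20)
  means_t <- means_c <- numeric(length(eff))
  for (i in seq_along(eff)) {
    cfg <- do.call(panel_config,
                   c(base, list(heating_effect = c(pm25 = eff[i]))))
    sp <- generate_panel(cfg)
    tr <- sp$truth[sp$truth$pollutant == "pm25", ]
    heat <- tr$heating > 0 & tr$city_id == "T01"
    hours_heat <- tr$timestamp %in% tr$timestamp[heat]
    means_t[i] <- mean(tr$observed[tr$city_id == "T01" & hours_heat])
    means_c[i] <- mean(tr$observed[tr$city_id == "C01" & hours_heat])
  }
  expect_true(all(diff(means_t) > 0))
  expect_lt(max(abs(diff(means_c))), 1e-9)
})

test_that("true weekly effect is the step in heating weeks, zero outside", {
  sp <- small_panel()
  tw <- true_weekly_effect(sp$truth, sp$calendar, sp$groups)
  expect_true(all(tw$value[tw$phase == "pre"] == 0))
  post <- tw$value[tw$phase == "post"]
  # every complete heating week carries the full step (all treated cities
  # share the common switch-on date, so no straddling weeks by default)
  expect_true(all(abs(post - 10) < 1e-9))
  # zero-effect generator gives an all-zero series
  cfg0 <- panel_config(n_control_cities = 2, n_treated_cities = 1,
                       n_alternative_cities = 0, seed = 2,
                       heating_effect = c(pm25 = 0))
  sp0 <- generate_panel(cfg0)
  tw0 <- true_weekly_effect(sp0$truth, sp0$calendar, sp0$groups)
  expect_true(all(tw0$value == 0))
})

test_that("a heating week straddling the boundary takes the time-weighted value", {
  # shift the group start 3 days past a week boundary by jittering the
  # calendar directly: rebuild blocks anchored 3 days before the true start
  sp <- small_panel()
  tr <- sp$truth[sp$truth$pollutant == "pm25" &
                   sp$truth$city_id == "T01", ]
  date <- as.Date(format(tr$timestamp, tz = "UTC"))
  blocks <- weekly_blocks(as.Date("2015-11-05"))  # true start is 2015-11-08
  daily <- tapply(tr$heating, date, mean)
  wk <- aggregate_weekly(as.Date(names(daily)), as.numeric(daily), blocks)
  straddle <- wk$value[wk$week_start == as.Date("2015-11-05")]
  # 3 of 7 days before switch-on: expected 10 * 4/7
  expect_equal(straddle, 10 * 4 / 7, tolerance = 1e-9)
})
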