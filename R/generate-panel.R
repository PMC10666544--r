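# Pollutant parameterisation of the generator. Baselines and amplitudes are
# typical of northern Chinese cities; units ug/m3 except CO (mg/m3).
pollutant_params <- function() {
  data.frame(
    pollutant = c("pm25", "so2", "no2", "co", "o3"),
    base      = c(45,     18,    30,    0.9,  55),
    seas_amp  = c(18,      8,    10,    0.30, -25),  # winter-positive except O3
    week_amp  = c(2.0,    0.8,   3.0,   0.05,  2.0),
    diel_amp  = c(6,       2,     6,    0.12, 15),
    diel_peak = c(22,     11,    20,     8,   15),   # local hour of diel maximum
    hol_amp   = c(10,      3,     2,    0.08,  0),
    floor     = c(2,      0.5,    1,    0.05,  2),
    stringsAsFactors = FALSE
  )
}

# AR(1) series with marginal standard deviation `sd` and lag-1 coefficient
# `phi` (default 0.95: hourly decorrelation time of about a day, typical of
# synoptic persistence).
ar1 <- function(n, sd = 1, phi = 0.95) {
  innov <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = rnorm(1, 0, sd)))
}

# Meteorology for one city: seasonal sinusoids plus AR(1) noise, with a winter
# temperature minimum, winter-shallow boundary layer, and a daytime solar
# cycle. `off` holds small persistent city offsets.
simulate_met <- function(doy, hod, off) {
  n <- length(doy)
  w <- cos(2 * pi * (doy - 15) / 365.25)           # +1 mid-January (winter)
  daylight <- pmax(0, sin(2 * pi * (hod - 6) / 24)) # 0 at 06/18, 1 at noon
  temp <- 13 + off["temp"] - 14 * w +
    4 * cos(2 * pi * (hod - 15) / 24) + ar1(n, 3)
  rh <- pmin(100, pmax(5, 60 + off["rh"] - 8 * w -
                         6 * cos(2 * pi * (hod - 4) / 24) + ar1(n, 10)))
  ws <- pmax(0.2, exp(0.8 + off["ws"] + 0.1 * w + ar1(n, 0.45)))
  wd <- (180 + off["wd"] + 90 * sin(2 * pi * doy / 365.25) +
           ar1(n, 55)) %% 360
  pressure <- 1013 + off["pressure"] + 8 * w + ar1(n, 4)
  tcc <- stats::plogis(0.2 - 0.4 * w + ar1(n, 1.1))
  blh <- pmax(50, 420 + off["blh"] - 230 * w +
                650 * daylight * (1 - 0.5 * tcc) + ar1(n, 110))
  ssr <- pmax(0, (550 - 250 * w) * daylight * (1 - 0.75 * tcc) * 3600 +
                ar1(n, 2e4))
  rain_on <- (tcc > 0.8) & (runif(n) < 0.25)
  tp <- ifelse(rain_on, rexp(n, 1 / (0.8 * (1.2 - 0.6 * w))), 0)
  data.frame(temp = temp, rh = rh, ws = ws, wd = wd, pressure = pressure,
             blh = blh, tcc = tcc, ssr = ssr, tp = tp)
}

# Smooth nonlinear meteorological modulation, as a log-scale driver g so the
# multiplier exp(scale * g) stays positive. Primary pollutants accumulate
# under shallow boundary layers and weak winds; ozone is driven by sunlight
# and temperature.
met_driver <- function(met, pollutant) {
  if (pollutant == "o3") {
    0.035 * (met$temp - 13) + 0.30 * (met$ssr / 2.5e6) +
      0.12 * log(pmax(met$blh, 50) / 450) - 0.03 * met$tp
  } else {
    0.45 * log(450 / pmax(met$blh, 50)) +
      0.35 * log(2.2 / pmax(met$ws, 0.2)) +
      0.004 * (met$rh - 60) - 0.05 * met$tp
  }
}

#' Generate a synthetic multi-city hourly panel with known decomposition
#'
#' Simulates hourly meteorology and pollutant concentrations for control,
#' treated and alternative cities over the configured window. Each pollutant
#' is built as `(baseline + trend + seasonal/weekly/diel/holiday emission
#' terms) * met multiplier * lognormal noise + additive heating step`, and
#' every component is recorded so that downstream estimators can be validated
#' by parameter recovery. Components sum exactly to the observed value at
#' every hour.
#'
#' The heating step is additive in concentration units (so the injected delta
#' is directly comparable to a synthetic-control difference), applied in
#' treated cities during heating dates and at `alternative_fraction` of the
#' step in alternative cities. Noise is multiplicative lognormal with mean 1
#' applied to the positive baseline before the step, preserving positivity
#' and the expected effect size.
#'
#' @param config A [panel_config()].
#' @return A list of class `synthetic_panel` with elements:
#' \describe{
#'   \item{panel}{`hourly_panel` data.frame: `city_id`, `timestamp` (POSIXct
#'     UTC), pollutants `pm25, so2, no2, co, o3`, meteorology `temp, rh, ws,
#'     wd, pressure, blh, tcc, ssr, tp`.}
#'   \item{truth}{`ground_truth` data.frame in long form: `city_id`,
#'     `timestamp`, `pollutant`, components `trend`, `seasonal`, `met`,
#'     `noise`, `heating`, and `observed` (their exact sum).}
#'   \item{calendar}{[heating_calendar()] rows for heating (treated and
#'     alternative) cities.}
#'   \item{groups}{[group_spec()] with groups `treated`, `nonheating`,
#'     `alternative` and populations.}
#' }
#' @export
#' @examples
#' cfg <- panel_config(n_control_cities = 2, n_treated_cities = 1,
#'                     n_alternative_cities = 0, seed = 7)
#' sp <- generate_panel(cfg)
#' head(sp$panel)
generate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed)
  pp <- pollutant_params()
  n_ctl <- config$n_control_cities
  n_trt <- config$n_treated_cities
  n_alt <- config$n_alternative_cities
  ids <- c(sprintf("C%02d", seq_len(n_ctl)),
           sprintf("T%02d", seq_len(n_trt)),
           if (n_alt > 0) sprintf("A%02d", seq_len(n_alt)))
  role <- rep(c("control", "treated", "alternative"),
              c(n_ctl, n_trt, n_alt))
  n_cities <- length(ids)
  pops <- config$populations
  if (is.null(pops)) pops <- rlnorm(n_cities, log(3e6), 0.5)
  names(pops) <- ids

  ts <- seq(as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(config$end_date, "23:00:00"), tz = "UTC"),
            by = "hour")
  n <- length(ts)
  date <- as.Date(format(ts, "%Y-%m-%d", tz = "UTC"))
  doy <- as.numeric(format(ts, "%j", tz = "UTC")) +
    as.numeric(format(ts, "%H", tz = "UTC")) / 24
  hod <- as.numeric(format(ts, "%H", tz = "UTC"))
  dow <- as.numeric(format(ts, "%u", tz = "UTC"))
  yrs_since <- as.numeric(ts - ts[1]) / (365.25 * 24 * 3600)
  ldoy <- lunar_day_of_year(date)
  w <- cos(2 * pi * (doy - 15) / 365.25)
  hol <- exp(-((ldoy - 3)^2) / (2 * 4^2))          # New-Year emission bump

  # heating calendar: common switch-on date per heating year (8 November by
  # default) with optional per-city jitter; end fixed at 30 April.
  labels <- config$heating_years
  heat_ids <- ids[role != "control"]
  cal <- NULL
  if (length(labels) > 0 && length(heat_ids) > 0) {
    jit <- config$heating_start_jitter_days
    rows <- expand.grid(city_id = heat_ids, heating_year = labels,
                        stringsAsFactors = FALSE)
    jd <- if (jit > 0) sample(seq(-jit, jit), nrow(rows), replace = TRUE)
          else rep(0L, nrow(rows))
    starts <- as.Date(sprintf("%d-11-08", rows$heating_year)) + jd
    ends <- as.Date(sprintf("%d-04-30", rows$heating_year + 1L))
    cal <- heating_calendar(rows$city_id, rows$heating_year, starts, ends)
  }

  panel_list <- vector("list", n_cities)
  truth_list <- vector("list", n_cities)
  for (ci in seq_len(n_cities)) {
    id <- ids[ci]
    off <- c(temp = rnorm(1, 0, 1.5), rh = rnorm(1, 0, 4),
             ws = rnorm(1, 0, 0.15), wd = runif(1, -40, 40),
             pressure = rnorm(1, 0, 2), blh = rnorm(1, 0, 40))
    met <- simulate_met(doy, hod, off)
    city_base_scale <- exp(rnorm(1, 0, 0.08))

    # hours inside this city's heating periods
    heat_on <- rep(FALSE, n)
    if (!is.null(cal)) {
      crows <- cal[cal$city_id == id, , drop = FALSE]
      for (k in seq_len(nrow(crows))) {
        heat_on <- heat_on | (date >= crows$start[k] & date <= crows$end[k])
      }
    }
    step_frac <- switch(role[ci], treated = 1,
                        alternative = config$alternative_fraction, control = 0)

    pdat <- data.frame(city_id = id, timestamp = ts)
    tlist <- vector("list", nrow(pp))
    for (pi in seq_len(nrow(pp))) {
      p <- pp[pi, ]
      slope <- config$trend_slope * p$base / 45 +
        if (role[ci] == "control") config$control_trend_offset * p$base / 45
        else 0
      trend_comp <- p$base * city_base_scale + slope * yrs_since
      seasonal_comp <- p$seas_amp * w +
        p$week_amp * cos(2 * pi * (dow - 2) / 7) +
        p$diel_amp * cos(2 * pi * (hod - p$diel_peak) / 24) +
        p$hol_amp * hol
      emission <- pmax(trend_comp + seasonal_comp, p$floor)
      # keep the recorded decomposition exact under flooring
      seasonal_comp <- emission - trend_comp
      g <- met_driver(met, p$pollutant)
      # additive met component, centered so its period mean is ~0; magnitude
      # scales with the pollutant baseline
      met_comp <- config$met_effect_scale * p$base * (g - mean(g))
      core <- pmax(emission + met_comp, p$floor)
      met_comp <- core - emission                  # exact under flooring
      eps <- if (config$noise_sd > 0) {
        exp(rnorm(n, -config$noise_sd^2 / 2, config$noise_sd))
      } else rep(1, n)
      noise_comp <- core * (eps - 1)
      heating_comp <- config$heating_effect[[p$pollutant]] * step_frac *
        as.numeric(heat_on)
      observed <- core * eps + heating_comp
      pdat[[p$pollutant]] <- observed
      tlist[[pi]] <- data.frame(
        city_id = id, timestamp = ts, pollutant = p$pollutant,
        trend = trend_comp, seasonal = seasonal_comp, met = met_comp,
        noise = noise_comp, heating = heating_comp, observed = observed,
        stringsAsFactors = FALSE)
    }
    panel_list[[ci]] <- cbind(pdat, met)
    truth_list[[ci]] <- do.call(rbind, tlist)
  }
  panel <- do.call(rbind, panel_list)
  rownames(panel) <- NULL
  class(panel) <- c("hourly_panel", "data.frame")
  truth <- do.call(rbind, truth_list)
  rownames(truth) <- NULL
  class(truth) <- c("ground_truth", "data.frame")

  groups <- group_spec(
    city_id = ids,
    group = c("nonheating", "treated", "alternative")[
      match(role, c("control", "treated", "alternative"))],
    role = role,
    population = as.numeric(pops))

  structure(list(panel = panel, truth = truth, calendar = cal,
                 groups = groups, config = config),
            class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat("synthetic hourly panel\n")
  cat(sprintf("  %d cities x %d hours (%s .. %s)\n",
              length(unique(x$panel$city_id)),
              length(unique(x$panel$timestamp)),
              format(min(x$panel$timestamp)), format(max(x$panel$timestamp))))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", names(table(x$groups$group)),
                            as.integer(table(x$groups$group))),
                    collapse = ", ")))
  invisible(x)
}

#' Population-weighted true weekly heating effect
#'
#' Averages the generator's recorded heating component across treated cities
#' (population-weighted) into the anchored week blocks of each heating year.
#' Zero outside heating periods; weeks straddling the heating boundary take
#' the time-weighted intermediate value.
#'
#' @param truth `ground_truth` from [generate_panel()].
#' @param calendar [heating_calendar()] for the heating cities.
#' @param groups [group_spec()] providing treated membership and populations.
#' @param pollutant Pollutant name (default `"pm25"`).
#' @return data.frame with `heating_year`, `week_start`, `phase`, `value`.
#' @export
true_weekly_effect <- function(truth, calendar, groups, pollutant = "pm25") {
  stopifnot(inherits(truth, "data.frame"))
  trt <- groups$city_id[groups$role == "treated"]
  if (length(trt) == 0) stop("no treated cities in groups")
  pops <- setNames(groups$population, groups$city_id)
  tt <- truth[truth$pollutant == pollutant & truth$city_id %in% trt,
              c("city_id", "timestamp", "heating")]
  wide <- panel_wide(tt$timestamp, tt$city_id, tt$heating)
  ts <- attr(wide, "timestamp")
  eff <- population_weighted(wide, pops)
  date <- as.Date(format(ts, "%Y-%m-%d", tz = "UTC"))
  out <- list()
  for (L in sort(unique(calendar$heating_year))) {
    gs <- group_heating_start(calendar, trt, L)
    blocks <- weekly_blocks(gs)
    daily <- tapply(eff, date, mean)
    dd <- data.frame(date = as.Date(names(daily)), value = as.numeric(daily))
    wk <- aggregate_weekly(dd$date, dd$value, blocks, min_days = 4L)
    wk$heating_year <- L
    out[[as.character(L)]] <- wk[, c("heating_year", "week_start", "phase",
                                     "value")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group-level heating start date
#'
#' The median heating start across a set of cities for one heating year
#' (cities may switch on a few days apart; the group boundary uses the
#' median date).
#'
#' @param calendar [heating_calendar()].
#' @param city_ids Cities defining the group.
#' @param heating_year Heating-year label.
#' @return A Date.
#' @export
group_heating_start <- function(calendar, city_ids, heating_year) {
  rows <- calendar[calendar$city_id %in% city_ids &
                     calendar$heating_year == heating_year, , drop = FALSE]
  if (nrow(rows) == 0) stop("no calendar entries for heating year ",
                            heating_year)
  as.Date(median(as.numeric(rows$start)), origin = "1970-01-01")
}
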