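#' Configuration for the synthetic hourly panel generator
#'
#' Bundles and validates every knob of [generate_panel()]. Defaults describe
#' the study conditions used throughout the package's validation suite:
#' 20 control cities, 8 treated cities, two complete heating years
#' (May 2015 - April 2017), a 10 ug/m3 PM2.5 heating enhancement, a declining
#' emission trend and moderate multiplicative noise.
#'
#' @param n_control_cities Number of control (non-heating) cities, >= 2.
#' @param n_treated_cities Number of treated (heating) cities, >= 1.
#' @param n_alternative_cities Number of "alternative" cities that receive a
#'   partial heating enhancement, >= 0.
#' @param start_date,end_date Panel window (Date or "YYYY-MM-DD"). The window
#'   must contain at least two complete heating years (1 May of a label year
#'   through 30 April of the next) when `require_ascm_years = TRUE`.
#' @param heating_effect Named numeric vector of per-pollutant heating-season
#'   concentration enhancements (ug/m3; mg/m3 for CO), applied as an additive
#'   step in treated cities during heating dates. All entries must be >= 0.
#' @param alternative_fraction Multiplier in (0, 1) applied to
#'   `heating_effect` in alternative cities.
#' @param met_effect_scale Dimensionless scale of the meteorological modulation
#'   of concentrations; 0 switches meteorology off.
#' @param trend_slope Linear emission trend for PM2.5 in ug/m3 per year
#'   (typically negative); other pollutants are scaled proportionally to their
#'   baseline level.
#' @param noise_sd Standard deviation (sdlog, dimensionless) of the
#'   multiplicative lognormal observation noise applied to the positive
#'   baseline; the noise has mean 1 so the additive heating step is preserved
#'   in expectation.
#' @param seed Integer RNG seed; identical configurations generate
#'   bit-identical panels.
#' @param populations Optional numeric vector of per-city populations
#'   (persons, > 0), recycled in order control, treated, alternative. By
#'   default populations are drawn lognormally around 3 million.
#' @param control_trend_offset Extra trend slope (ug/m3 per year, PM2.5 scale)
#'   added to control cities only; 0 keeps control and treated trends
#'   identical (comparable non-heating behaviour), nonzero values stress-test
#'   the estimator with divergent trends.
#' @param heating_start_jitter_days Half-width (days) of a uniform per-city
#'   jitter of the heating start date around the common start (default 0: all
#'   heating cities switch on together, so the group treatment boundary is
#'   sharp).
#' @param require_ascm_years If `TRUE` (default), fail when the window holds
#'   fewer than two complete heating years, the minimum for the year-by-year
#'   synthetic control design.
#'
#' @return An object of class `panel_config` (a validated list).
#' @export
#' @examples
#' cfg <- panel_config(n_control_cities = 4, n_treated_cities = 2,
#'                     start_date = "2015-05-01", end_date = "2017-04-30")
panel_config <- function(n_control_cities = 20,
                         n_treated_cities = 8,
                         n_alternative_cities = 3,
                         start_date = "2015-05-01",
                         end_date = "2017-04-30",
                         heating_effect = c(pm25 = 10, so2 = 5, no2 = 0,
                                            co = 0.12, o3 = 3),
                         alternative_fraction = 0.4,
                         met_effect_scale = 1,
                         trend_slope = -3,
                         noise_sd = 0.25,
                         seed = 1L,
                         populations = NULL,
                         control_trend_offset = 0,
                         heating_start_jitter_days = 0L,
                         require_ascm_years = TRUE) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  stopifnot(
    length(n_control_cities) == 1, n_control_cities >= 2,
    length(n_treated_cities) == 1, n_treated_cities >= 1,
    length(n_alternative_cities) == 1, n_alternative_cities >= 0,
    !is.na(start_date), !is.na(end_date)
  )
  if (start_date >= end_date) stop("start_date must precede end_date")
  full <- c(pm25 = 0, so2 = 0, no2 = 0, co = 0, o3 = 0)
  if (is.null(names(heating_effect)) ||
      !all(names(heating_effect) %in% names(full))) {
    stop("heating_effect must be named with pollutants among: ",
         paste(names(full), collapse = ", "))
  }
  full[names(heating_effect)] <- heating_effect
  if (any(full < 0)) stop("heating_effect must be >= 0")
  if (alternative_fraction <= 0 || alternative_fraction >= 1) {
    stop("alternative_fraction must lie in (0, 1)")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n_cities <- n_control_cities + n_treated_cities + n_alternative_cities
  if (!is.null(populations)) {
    if (length(populations) != n_cities) {
      stop("populations must have one entry per city (", n_cities, ")")
    }
    if (any(populations <= 0)) stop("populations must be > 0")
  }
  labels <- heating_year_labels(start_date, end_date)
  if (require_ascm_years && length(labels) < 2) {
    stop("date range holds ", length(labels), " complete heating year(s); ",
         "at least 2 are required for the year-by-year ASCM design ",
         "(set require_ascm_years = FALSE to override)")
  }
  structure(list(
    n_control_cities = as.integer(n_control_cities),
    n_treated_cities = as.integer(n_treated_cities),
    n_alternative_cities = as.integer(n_alternative_cities),
    start_date = start_date, end_date = end_date,
    heating_effect = full,
    alternative_fraction = alternative_fraction,
    met_effect_scale = met_effect_scale,
    trend_slope = trend_slope,
    noise_sd = noise_sd,
    seed = as.integer(seed),
    populations = populations,
    control_trend_offset = control_trend_offset,
    heating_start_jitter_days = as.integer(heating_start_jitter_days),
    heating_years = labels
  ), class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat("synthetic panel configuration\n")
  cat(sprintf("  cities: %d control + %d treated + %d alternative\n",
              x$n_control_cities, x$n_treated_cities, x$n_alternative_cities))
  cat(sprintf("  window: %s .. %s (%d complete heating years)\n",
              format(x$start_date), format(x$end_date),
              length(x$heating_years)))
  he <- x$heating_effect[x$heating_effect > 0]
  cat("  heating effect:",
      if (length(he)) paste(names(he), he, sep = "=", collapse = ", ")
      else "none", "\n")
  cat(sprintf("  trend %.2f /yr, met scale %.2f, noise sdlog %.2f, seed %d\n",
              x$trend_slope, x$met_effect_scale, x$noise_sd, x$seed))
  invisible(x)
}

#' Heating-year labels fully contained in a window
#'
#' A heating year labelled `L` spans 1 May of `L` to 30 April of `L + 1`
#' (pre period plus heating period). The label is included when that whole
#' span lies inside `[start, end]`.
#'
#' @param start,end Window boundaries (Date).
#' @return Integer vector of labels (possibly empty).
#' @export
heating_year_labels <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  yrs <- seq(as.integer(format(start, "%Y")) - 1L,
             as.integer(format(end, "%Y")))
  keep <- vapply(yrs, function(L) {
    as.Date(sprintf("%d-05-01", L)) >= start &&
      as.Date(sprintf("%d-04-30", L + 1L)) <= end
  }, logical(1))
  yrs[keep]
}
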