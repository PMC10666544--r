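#' Heating calendar
#'
#' Per-city heating periods keyed by heating-year label. A heating year
#' labelled `L` starts on a city-specific date in October or November of `L`
#' and ends on 30 April of `L + 1`; its pre-treatment period starts on
#' 1 May of `L`.
#'
#' @param city_id Character vector of city identifiers.
#' @param heating_year Integer vector of heating-year labels.
#' @param start,end Date vectors of heating start and end dates.
#' @return A data.frame of class `heating_calendar` with columns `city_id`,
#'   `heating_year`, `start`, `end`.
#' @export
heating_calendar <- function(city_id, heating_year, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  heating_year <- as.integer(heating_year)
  stopifnot(length(city_id) == length(heating_year),
            length(city_id) == length(start),
            length(city_id) == length(end))
  if (any(start >= end)) stop("heating start must precede end")
  mo <- as.integer(format(start, "%m"))
  if (!all(mo %in% c(10L, 11L))) {
    stop("heating start dates must fall in October or November")
  }
  if (!all(as.integer(format(start, "%Y")) == heating_year)) {
    stop("heating start must fall in its label year")
  }
  exp_end <- as.Date(sprintf("%d-04-30", heating_year + 1L))
  if (!all(end == exp_end)) {
    stop("heating end must be 30 April of the year after the label")
  }
  structure(data.frame(city_id = as.character(city_id),
                       heating_year = heating_year,
                       start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("heating_calendar", "data.frame"))
}

#' Group specification
#'
#' Assigns cities to named analysis groups with a causal role and a
#' population weight. Control groups must have at least two members.
#'
#' @param city_id Character vector of city identifiers.
#' @param group Character vector of group names (e.g. `"two_plus_26"`,
#'   `"northern"`, `"nonheating"`, `"alternative"`, or the synthetic panel's
#'   `"treated"`).
#' @param role One of `"treated"`, `"control"`, `"alternative"` per city.
#' @param population Positive population weights (persons).
#' @return A data.frame of class `group_spec`.
#' @export
group_spec <- function(city_id, group, role, population) {
  n <- length(city_id)
  if (length(group) == 1) group <- rep(group, n)
  if (length(role) == 1) role <- rep(role, n)
  stopifnot(length(group) == n, length(role) == n, length(population) == n)
  role <- match.arg(role, c("treated", "control", "alternative"),
                    several.ok = TRUE)
  if (any(population <= 0)) stop("populations must be > 0")
  if (sum(role == "control") > 0 && sum(role == "control") < 2) {
    stop("a control group needs at least 2 member cities")
  }
  structure(data.frame(city_id = as.character(city_id),
                       group = as.character(group),
                       role = role, population = population,
                       stringsAsFactors = FALSE),
            class = c("group_spec", "data.frame"))
}

#' Total oxidant from NO2 and O3 mass concentrations
#'
#' Ox is the sum of NO2 and O3 expressed as volume mixing ratios. Mass
#' concentrations are converted at 25 degC and 1013 hPa (the post-2018 Chinese
#' reference state): 1 ppb NO2 = 1.88 ug/m3, 1 ppb O3 = 1.96 ug/m3.
#'
#' @param no2,o3 Non-negative mass concentrations in ug/m3 (vectorized;
#'   `NA` propagates).
#' @return Ox in ppbv.
#' @export
#' @examples
#' compute_ox(18.8, 19.6) # 10 + 10 = 20 ppbv
compute_ox <- function(no2, o3) {
  if (any(no2 < 0, na.rm = TRUE) || any(o3 < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0")
  }
  no2 / 1.88 + o3 / 1.96
}

#' Daily maximum 8-hour mean (MDA8)
#'
#' For each calendar day, the maximum over the 24 window-start hours of the
#' forward 8-hour mean. A window is valid with at least 6 of its 8 hours
#' present; a day is valid with at least 18 valid windows, otherwise `NA`.
#' Windows starting late in the day reach into the first 7 hours of the next
#' day, which are used when available.
#'
#' @param timestamp POSIXct hourly timestamps (UTC), sorted, for one city.
#' @param value Hourly concentrations aligned with `timestamp` (O3 in the
#'   motivating application); `NA` allowed.
#' @param min_hours_window Minimum present hours for a valid window (default 6).
#' @param min_windows Minimum valid windows for a valid day (default 18).
#' @return data.frame with columns `date` and `mda8`.
#' @export
compute_mda8 <- function(timestamp, value, min_hours_window = 6L,
                         min_windows = 18L) {
  stopifnot(inherits(timestamp, "POSIXct"), length(timestamp) == length(value))
  o <- order(timestamp)
  timestamp <- timestamp[o]; value <- value[o]
  # place values on a complete hourly grid so window arithmetic is positional
  grid <- seq(min(timestamp), max(timestamp), by = "hour")
  v <- rep(NA_real_, length(grid))
  v[match(timestamp, grid)] <- value
  n <- length(v)
  ok <- !is.na(v)
  v0 <- ifelse(ok, v, 0)
  # forward 8-hour sums / counts at each window start
  csum <- cumsum(c(0, v0)); ccnt <- cumsum(c(0, as.numeric(ok)))
  starts <- seq_len(n)
  ends <- pmin(starts + 7L, n)
  wsum <- csum[ends + 1L] - csum[starts]
  wcnt <- ccnt[ends + 1L] - ccnt[starts]
  # truncated trailing windows (< 8 grid hours) can still be valid if >= 6 present
  wmean <- ifelse(wcnt >= min_hours_window, wsum / wcnt, NA_real_)
  day <- as.Date(format(grid, "%Y-%m-%d", tz = "UTC"))
  valid <- !is.na(wmean)
  nwin <- tapply(valid, day, sum)
  mx <- tapply(wmean, day, function(z) if (all(is.na(z))) NA_real_ else
    max(z, na.rm = TRUE))
  res <- data.frame(date = as.Date(names(mx)),
                    mda8 = ifelse(as.numeric(nwin) >= min_windows,
                                  as.numeric(mx), NA_real_))
  rownames(res) <- NULL
  res
}

#' Hourly to daily aggregation
#'
#' Daily means requiring a minimum number of valid hours (default 18 of 24,
#' common regulatory practice); days below the threshold are `NA`.
#'
#' @param timestamp POSIXct hourly timestamps (UTC).
#' @param value Hourly values; `NA` allowed.
#' @param min_hours Minimum valid hours per day (default 18). When deweathered
#'   values are computed on a reduced hourly grid, pass the grid's expected
#'   per-day count.
#' @return data.frame with columns `date`, `value`, `n_hours`.
#' @export
aggregate_daily <- function(timestamp, value, min_hours = 18L) {
  stopifnot(inherits(timestamp, "POSIXct"), length(timestamp) == length(value))
  day <- as.Date(format(timestamp, "%Y-%m-%d", tz = "UTC"))
  nh <- tapply(!is.na(value), day, sum)
  mn <- tapply(value, day, mean, na.rm = TRUE)
  out <- data.frame(date = as.Date(names(mn)),
                    value = ifelse(as.numeric(nh) >= min_hours,
                                   as.numeric(mn), NA_real_),
                    n_hours = as.integer(nh))
  rownames(out) <- NULL
  out[order(out$date), , drop = FALSE]
}

#' Week blocks anchored to a heating start date
#'
#' Consecutive 7-day blocks counted backward from the heating start (pre) and
#' forward from it (post), covering the heating-year window
#' `[1 May label, 1 May label+1)`. Intervals are half-open `[start, start+7)`;
#' partial terminal blocks are dropped.
#'
#' @param heating_start Heating switch-on date (Date).
#' @param window_start First date of the window (default 1 May of the label
#'   year).
#' @param window_end_excl First date after the window (default 1 May of the
#'   following year, i.e. the day after the 30 April heating end).
#' @return data.frame with columns `week_start` (Date) and `phase`
#'   (`"pre"`/`"post"`).
#' @export
weekly_blocks <- function(heating_start,
                          window_start = NULL, window_end_excl = NULL) {
  heating_start <- as.Date(heating_start)
  label <- as.integer(format(heating_start, "%Y"))
  if (is.null(window_start)) {
    window_start <- as.Date(sprintf("%d-05-01", label))
  }
  if (is.null(window_end_excl)) {
    window_end_excl <- as.Date(sprintf("%d-05-01", label + 1L))
  }
  n_pre <- as.integer(floor(as.numeric(heating_start - window_start) / 7))
  n_post <- as.integer(floor(as.numeric(window_end_excl - heating_start) / 7))
  pre_starts <- heating_start - 7 * rev(seq_len(n_pre))
  post_starts <- heating_start + 7 * (seq_len(n_post) - 1L)
  data.frame(week_start = c(pre_starts, post_starts),
             phase = rep(c("pre", "post"), c(n_pre, n_post)),
             stringsAsFactors = FALSE)
}

#' Daily to weekly aggregation on anchored blocks
#'
#' Weekly means over the blocks of [weekly_blocks()], requiring a minimum
#' number of valid days per block (default 4 of 7).
#'
#' @param date Date vector of daily observations.
#' @param value Daily values; `NA` allowed.
#' @param blocks data.frame from [weekly_blocks()].
#' @param min_days Minimum valid days per week (default 4).
#' @return `blocks` with columns `value` and `n_days` appended.
#' @export
aggregate_weekly <- function(date, value, blocks, min_days = 4L) {
  stopifnot(inherits(date, "Date"), length(date) == length(value))
  idx <- findInterval(as.numeric(date), as.numeric(blocks$week_start))
  inblock <- rep(FALSE, length(idx))
  ok <- idx >= 1 & idx <= nrow(blocks)
  inblock[ok] <- as.numeric(date[ok]) <
    as.numeric(blocks$week_start[idx[ok]]) + 7
  idx[!inblock] <- NA
  f <- factor(idx, levels = seq_len(nrow(blocks)))
  nd <- tapply(!is.na(value), f, sum)
  nd[is.na(nd)] <- 0
  mn <- tapply(value, f, mean, na.rm = TRUE)
  out <- blocks
  out$value <- ifelse(as.numeric(nd) >= min_days, as.numeric(mn), NA_real_)
  out$n_days <- as.integer(nd)
  out
}

# wide timestamps x cities matrix from long vectors (missing cells NA)
panel_wide <- function(timestamp, city, value) {
  cities <- sort(unique(city))
  ts <- sort(unique(timestamp))
  m <- matrix(NA_real_, length(ts), length(cities),
              dimnames = list(NULL, cities))
  m[cbind(match(timestamp, ts), match(city, cities))] <- value
  attr(m, "timestamp") <- ts
  m
}

#' Population-weighted group series
#'
#' Weighted mean over cities with data at each timestamp,
#' `sum(w_i x_i) / sum(w_i)` with `w_i` the city population. Timestamps where
#' every city is missing yield `NA`.
#'
#' @param values Matrix of city series, cities in columns (column names are
#'   city ids), timestamps in rows.
#' @param populations Named numeric vector of populations covering every
#'   column of `values`.
#' @return Numeric vector, one value per row.
#' @export
population_weighted <- function(values, populations) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("values must have city-id column names")
  if (!all(colnames(values) %in% names(populations))) {
    stop("every city needs a population")
  }
  w <- populations[colnames(values)]
  if (any(w <= 0)) stop("populations must be > 0")
  ok <- !is.na(values)
  num <- (ifelse(ok, values, 0)) %*% w
  den <- ok %*% w
  out <- as.numeric(num) / as.numeric(den)
  out[as.numeric(den) == 0] <- NA_real_
  out
}

#' Split a weekly series into pre- and post-treatment blocks
#'
#' The pre period runs from 1 May of the heating-year label to the heating
#' start (exclusive); the post period from the heating start (inclusive,
#' half-open week convention) to 30 April of the next year.
#'
#' @param weekly data.frame with columns `week_start`, `phase`, `value`
#'   (as returned by [aggregate_weekly()]).
#' @param min_weeks Minimum number of weeks required in each block (default 8).
#' @return list with elements `pre` and `post` (data.frames).
#' @export
split_periods <- function(weekly, min_weeks = 8L) {
  stopifnot(all(c("week_start", "phase", "value") %in% names(weekly)))
  pre <- weekly[weekly$phase == "pre", , drop = FALSE]
  post <- weekly[weekly$phase == "post", , drop = FALSE]
  if (nrow(pre) < min_weeks || nrow(post) < min_weeks) {
    stop(sprintf(
      "insufficient weeks for fit/effect estimation: %d pre, %d post (need >= %d each)",
      nrow(pre), nrow(post), min_weeks))
  }
  list(pre = pre, post = post)
}
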