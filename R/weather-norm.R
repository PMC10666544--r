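MET_VARS <- c("temp", "rh", "ws", "wd", "pressure", "blh", "tcc", "ssr", "tp")
TIME_VARS <- c("unix_trend", "day_of_year", "lunar_day_of_year",
               "day_of_week", "hour_of_day")

#' Random-forest configuration for weather normalization
#'
#' Hyperparameters of the deweathering forest: 300 trees, minimum terminal
#' node size 5, a seeded random 70/30 train/test row split, and 1000
#' meteorological resampling draws per deweathered value.
#'
#' @param n_tree Number of trees (default 300).
#' @param min_node_size Minimum terminal node size (default 5).
#' @param train_frac Fraction of valid rows used for training (default 0.70).
#' @param n_resample Number of meteorological resampling draws averaged per
#'   deweathered value (default 1000).
#' @param seed RNG seed controlling both the split and the resampling draws.
#' @param resample_window_days Half-width, in days of the year (circular), of
#'   the seasonal window from which meteorological states are resampled
#'   (default 21): the pool for an hour contains all valid hours of any year
#'   whose day of year lies within this distance. `Inf` resamples from the
#'   whole observation period. The windowed default averages out synoptic
#'   variability while preserving each site's seasonal meteorological climate,
#'   which keeps emission seasonality (and step interventions) out of the
#'   meteorological attribution; see the methods vignette.
#' @param chronological_split Use the first `train_frac` of rows in time order
#'   instead of a random split (default `FALSE`, matching the reference
#'   workflow).
#' @param log_target Train on `log(target)` and back-transform predictions
#'   (default `FALSE`: raw concentration scale).
#' @return Object of class `rf_config`.
#' @export
rf_config <- function(n_tree = 300L, min_node_size = 5L, train_frac = 0.70,
                      n_resample = 1000L, seed = 1L,
                      resample_window_days = 21,
                      chronological_split = FALSE, log_target = FALSE) {
  stopifnot(n_tree >= 1, min_node_size >= 1,
            train_frac > 0, train_frac < 1, n_resample >= 0,
            resample_window_days > 0)
  structure(list(n_tree = as.integer(n_tree),
                 min_node_size = as.integer(min_node_size),
                 train_frac = train_frac,
                 n_resample = as.integer(n_resample),
                 seed = as.integer(seed),
                 resample_window_days = resample_window_days,
                 chronological_split = chronological_split,
                 log_target = log_target),
            class = "rf_config")
}

#' Build the deweathering feature table for one city
#'
#' One row per hour with the 9 meteorological features and 5 time features
#' (Unix time as linear trend, Gregorian day of year as seasonal component,
#' lunar day of year as holiday component, day of week, hour of day). Rows
#' with any missing meteorological value are flagged (`met_ok = FALSE`) and
#' excluded from training and from resampling draws.
#'
#' @param panel `hourly_panel` rows for one city (sorted timestamps).
#' @param lunar_table Year to Lunar New Year mapping
#'   ([lunar_new_year_dates()]); must cover the panel years.
#' @return data.frame with `timestamp`, the 14 features, and `met_ok`.
#' @export
build_features <- function(panel, lunar_table = lunar_new_year_dates()) {
  stopifnot(all(c("timestamp", MET_VARS) %in% names(panel)))
  if (length(unique(panel$city_id)) > 1) {
    stop("build_features expects a single city's rows")
  }
  ts <- panel$timestamp
  if (is.unsorted(ts)) stop("panel timestamps must be sorted")
  date <- as.Date(format(ts, "%Y-%m-%d", tz = "UTC"))
  feats <- data.frame(
    timestamp = ts,
    unix_trend = as.numeric(ts),
    day_of_year = as.integer(format(ts, "%j", tz = "UTC")),
    lunar_day_of_year = lunar_day_of_year(date, lunar_table),
    day_of_week = as.integer(format(ts, "%u", tz = "UTC")),
    hour_of_day = as.integer(format(ts, "%H", tz = "UTC"))
  )
  for (v in MET_VARS) feats[[v]] <- panel[[v]]
  feats$met_ok <- stats::complete.cases(feats[, MET_VARS])
  feats
}

#' Train a deweathering random forest for one pollutant
#'
#' Fits a regression forest of the target concentration on the 14 features,
#' on a seeded 70% row split of the valid rows; reports Pearson correlation,
#' mean bias (predicted minus observed) and RMSE on the held-out 30%.
#'
#' @param features Feature table from [build_features()].
#' @param target Hourly concentration vector aligned with `features`
#'   (`NA` allowed; such rows are excluded).
#' @param cfg An [rf_config()].
#' @param min_rows Minimum number of valid rows required (default 1000).
#' @return list of class `deweather_model` with elements `forest` (ranger
#'   object), `metrics` (list `r`, `bias`, `rmse`, `n_train`, `n_test`),
#'   `cfg`, and the training feature names.
#' @export
train_rf <- function(features, target, cfg = rf_config(), min_rows = 1000L) {
  stopifnot(length(target) == nrow(features))
  valid <- features$met_ok & !is.na(target)
  n_valid <- sum(valid)
  if (n_valid < min_rows) {
    stop("only ", n_valid, " valid rows; need >= ", min_rows)
  }
  dat <- features[valid, c(TIME_VARS, MET_VARS)]
  y <- target[valid]
  if (cfg$log_target) {
    if (any(y <= 0)) stop("log_target requires strictly positive target")
    y <- log(y)
  }
  dat$.y <- y
  n <- nrow(dat)
  n_train <- max(1L, round(cfg$train_frac * n))
  set.seed(cfg$seed)
  idx <- if (cfg$chronological_split) seq_len(n_train)
         else sample.int(n, n_train)
  train <- dat[idx, ]; test <- dat[-idx, ]
  forest <- ranger::ranger(
    dependent.variable.name = ".y", data = train,
    num.trees = cfg$n_tree, min.node.size = cfg$min_node_size,
    seed = cfg$seed, num.threads = 1L, verbose = FALSE,
    respect.unordered.factors = FALSE)
  pred <- predict(forest, test[, c(TIME_VARS, MET_VARS)],
                  num.threads = 1L, verbose = FALSE)$predictions
  obs <- test$.y
  if (cfg$log_target) { pred <- exp(pred); obs <- exp(obs) }
  r <- if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    warning("constant target or prediction on held-out set; r undefined, set to 0")
    0
  } else stats::cor(pred, obs)
  metrics <- list(r = r,
                  bias = mean(pred - obs),
                  rmse = sqrt(mean((pred - obs)^2)),
                  n_train = nrow(train), n_test = nrow(test))
  structure(list(forest = forest, metrics = metrics, cfg = cfg,
                 feature_names = c(TIME_VARS, MET_VARS)),
            class = "deweather_model")
}

#' @export
print.deweather_model <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "deweathering forest: %d trees | held-out r = %.3f, bias = %.3f, rmse = %.3f (n = %d/%d)\n",
    x$forest$num.trees, m$r, m$bias, m$rmse, m$n_train, m$n_test))
  invisible(x)
}

#' Deweather a concentration series by meteorological resampling
#'
#' For each evaluation hour, the 9 meteorological features are replaced
#' `n_resample` times by the meteorology of hours drawn uniformly (with
#' replacement, seeded) from the resampling pool, keeping the hour's 5 time
#' features fixed; the deweathered value is the mean of the resulting forest
#' predictions. Whole meteorological rows are drawn jointly so cross-variable
#' correlation (boundary layer with temperature, wind speed with direction)
#' is preserved; hours with missing meteorology are never drawn.
#'
#' By default the pool for an hour is restricted to the same season: all
#' valid hours of any year within `resample_window_days` days of the year
#' (circularly). This averages out synoptic weather while preserving the
#' site's seasonal meteorological climate, so seasonal emission signal that a
#' forest partly encodes in seasonal meteorological proxies is not stripped
#' from the deweathered series. Setting `resample_window_days = Inf` draws
#' from the whole observation period instead, which removes the seasonal
#' meteorological cycle as well (see the methods vignette for the trade-off).
#'
#' @param model A `deweather_model` from [train_rf()].
#' @param features Feature table from [build_features()] spanning the
#'   observation period (the resampling pool).
#' @param cfg An [rf_config()]; `cfg$n_resample` and `cfg$seed` control the
#'   draws. Must have `n_resample >= 1`.
#' @param at Optional POSIXct subset of `features$timestamp` at which to
#'   evaluate the deweathered series (default: all hours). Evaluating on a
#'   reduced, evenly spaced grid (e.g. every 6th hour) is an unbiased way to
#'   cut compute for daily/weekly aggregation.
#' @param clip_negative Clip negative deweathered values to 0 at reporting
#'   (after averaging, never inside it). Default `TRUE`.
#' @return data.frame of class `deweathered_series`: `timestamp`, `value`,
#'   attribute `n_resample`.
#' @export
deweather <- function(model, features, cfg = model$cfg, at = NULL,
                      clip_negative = TRUE) {
  stopifnot(inherits(model, "deweather_model"))
  if (cfg$n_resample < 1) stop("n_resample must be >= 1")
  pool <- which(features$met_ok)
  if (length(pool) == 0) stop("no valid meteorology rows to resample from")
  if (is.null(at)) at <- features$timestamp
  rows <- match(at, features$timestamp)
  if (anyNA(rows)) stop("`at` must be a subset of features$timestamp")
  Tn <- length(rows)
  base <- features[rows, c(TIME_VARS, MET_VARS)]
  window <- cfg$resample_window_days
  if (is.null(window)) window <- Inf
  if (is.finite(window)) {
    # seasonal pools keyed by day of year (circular distance)
    pool_doy <- features$day_of_year[pool]
    doys <- sort(unique(base$day_of_year))
    pools <- lapply(doys, function(d) {
      dd <- abs(pool_doy - d)
      p <- pool[pmin(dd, 366 - dd) <= window]
      if (length(p) == 0) stop("empty seasonal resampling pool at day ", d)
      p
    })
    names(pools) <- doys
    grp <- split(seq_len(Tn), base$day_of_year)
  }
  acc <- numeric(Tn)
  set.seed(cfg$seed + 1L)
  # batch draws into chunks so prediction is a few large calls rather than
  # n_resample small ones (identical draws; only the call grouping differs)
  chunk <- max(1L, min(cfg$n_resample, floor(3e5 / Tn)))
  b_done <- 0L
  while (b_done < cfg$n_resample) {
    nb <- min(chunk, cfg$n_resample - b_done)
    draws <- integer(nb * Tn)
    for (j in seq_len(nb)) {
      draw <- if (is.finite(window)) {
        d <- integer(Tn)
        for (g in names(grp)) {
          p <- pools[[g]]
          d[grp[[g]]] <- p[sample.int(length(p), length(grp[[g]]),
                                      replace = TRUE)]
        }
        d
      } else {
        pool[sample.int(length(pool), Tn, replace = TRUE)]
      }
      draws[seq_len(Tn) + (j - 1L) * Tn] <- draw
    }
    x <- base[rep.int(seq_len(Tn), nb), ]
    x[, MET_VARS] <- features[draws, MET_VARS]
    p <- predict(model$forest, x, num.threads = 1L,
                 verbose = FALSE)$predictions
    if (cfg$log_target) p <- exp(p)
    acc <- acc + rowSums(matrix(p, nrow = Tn))
    b_done <- b_done + nb
  }
  val <- acc / cfg$n_resample
  if (clip_negative) val <- pmax(val, 0)
  structure(data.frame(timestamp = at, value = val),
            class = c("deweathered_series", "data.frame"),
            n_resample = cfg$n_resample)
}

#' Weather effect: observed minus deweathered
#'
#' The meteorology-driven part of the observed series. Requires aligned
#' timestamps; missing values propagate.
#'
#' @param observed data.frame with `timestamp`, `value` (or an `hourly_panel`
#'   column passed as a vector alongside `timestamp`).
#' @param deweathered `deweathered_series` from [deweather()].
#' @return data.frame `timestamp`, `value` (observed - deweathered).
#' @export
weather_effect <- function(observed, deweathered) {
  stopifnot(all(c("timestamp", "value") %in% names(observed)),
            all(c("timestamp", "value") %in% names(deweathered)))
  if (nrow(observed) != nrow(deweathered) ||
      !all(observed$timestamp == deweathered$timestamp)) {
    stop("observed and deweathered series are not aligned")
  }
  data.frame(timestamp = observed$timestamp,
             value = observed$value - deweathered$value)
}
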