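# circular-aware population weighting of wind direction
weighted_wd <- function(wd_mat, populations) {
  s <- population_weighted(sin(wd_mat * pi / 180), populations)
  c_ <- population_weighted(cos(wd_mat * pi / 180), populations)
  (atan2(s, c_) * 180 / pi) %% 360
}

# Population-weighted "virtual city" built from member cities: every pollutant
# and meteorological column is averaged hour by hour (wind direction via the
# vector mean).
aggregate_group_unit <- function(panel, city_ids, populations,
                                 unit_id = "GROUP") {
  sub <- panel[panel$city_id %in% city_ids, , drop = FALSE]
  ts <- sort(unique(sub$timestamp))
  out <- data.frame(city_id = unit_id, timestamp = ts)
  vars <- c("pm25", "so2", "no2", "co", "o3", MET_VARS)
  for (v in vars) {
    wide <- panel_wide(sub$timestamp, sub$city_id, sub[[v]])
    out[[v]] <- if (v == "wd") weighted_wd(wide, populations)
                else population_weighted(wide, populations)
  }
  class(out) <- c("hourly_panel", "data.frame")
  out
}

#' Deweather one city (or group unit) and aggregate to daily means
#'
#' Trains the random forest on the unit's hourly series and evaluates the
#' deweathered concentration on an evenly spaced hourly grid (`stride` hours
#' apart; even diel sampling keeps daily means unbiased), then aggregates to
#' daily values.
#'
#' @param unit `hourly_panel` rows for one unit.
#' @param pollutant Column name of the target pollutant.
#' @param cfg [rf_config()].
#' @param stride Hour spacing of the deweathering grid (1 = every hour).
#' @param min_rows Minimum valid training rows (see [train_rf()]).
#' @param daily_stat `"mean"` (default) or `"mda8"` (daily maximum 8-hour
#'   mean, the ozone convention; requires `stride = 1`).
#' @return list: `daily` (data.frame `date`, `value`), `metrics`, `model`.
#' @export
deweather_unit <- function(unit, pollutant, cfg = rf_config(), stride = 1L,
                           min_rows = 1000L,
                           daily_stat = c("mean", "mda8")) {
  daily_stat <- match.arg(daily_stat)
  if (daily_stat == "mda8" && stride != 1L) {
    stop("MDA8 needs the full hourly grid; use stride = 1")
  }
  feats <- build_features(unit)
  model <- train_rf(feats, unit[[pollutant]], cfg, min_rows = min_rows)
  hod <- as.integer(format(feats$timestamp, "%H", tz = "UTC"))
  at <- feats$timestamp[hod %% stride == 0]
  dw <- deweather(model, feats, cfg, at = at)
  daily <- if (daily_stat == "mda8") {
    md <- compute_mda8(dw$timestamp, dw$value)
    data.frame(date = md$date, value = md$mda8)
  } else {
    per_day <- length(unique(hod[hod %% stride == 0]))
    aggregate_daily(dw$timestamp, dw$value,
                    min_hours = max(1L, floor(0.75 * per_day)))
  }
  list(daily = daily[, c("date", "value")], metrics = model$metrics,
       model = model)
}

#' End-to-end heating-impact estimation on a panel
#'
#' Runs the full two-stage workflow for one pollutant: deweather the treated
#' group unit (population-weighted across treated cities) and every control
#' city, aggregate to anchored weekly series per heating year, fit the ridge
#' ASCM year by year, and collect the synthetic-difference effect series.
#'
#' @param panel `hourly_panel` covering all cities.
#' @param calendar [heating_calendar()] for the heating cities.
#' @param groups [group_spec()].
#' @param pollutant Pollutant column (default `"pm25"`).
#' @param rf_cfg [rf_config()] for deweathering. Set `rf_cfg = NULL` to run
#'   the synthetic control on observed (not deweathered) concentrations.
#' @param stride Deweathering grid spacing in hours (default 3).
#' @param lambda_grid Optional ridge penalty grid.
#' @param jackknife Attach Jackknife+ bands (default `TRUE`).
#' @param placebo Also run the in-place placebo scan per heating year
#'   (default `FALSE`).
#' @param min_rows Minimum training rows per unit forest.
#' @param daily_stat Daily statistic, `"mean"` or `"mda8"` (ozone; requires
#'   `stride = 1`). See [deweather_unit()].
#' @return list of class `heating_impact`: `fits` (per heating year),
#'   `effects` (`effect_series`), `summary` ([summarize_effects()] result),
#'   `weekly` (unit x week table), `metrics` (per unit), `placebo`
#'   (per year, if requested).
#' @export
estimate_heating_impact <- function(panel, calendar, groups,
                                    pollutant = "pm25",
                                    rf_cfg = rf_config(), stride = 3L,
                                    lambda_grid = NULL, jackknife = TRUE,
                                    placebo = FALSE, min_rows = 1000L,
                                    daily_stat = c("mean", "mda8")) {
  daily_stat <- match.arg(daily_stat)
  treated_ids <- groups$city_id[groups$role == "treated"]
  control_ids <- groups$city_id[groups$role == "control"]
  if (length(treated_ids) < 1) stop("no treated cities")
  if (length(control_ids) < 2) stop("need >= 2 control cities")
  pops <- setNames(groups$population, groups$city_id)

  units <- list(TREATED = aggregate_group_unit(panel, treated_ids,
                                               pops[treated_ids], "TREATED"))
  for (id in control_ids) {
    units[[id]] <- panel[panel$city_id == id, , drop = FALSE]
  }

  metrics <- list()
  daily <- list()
  for (nm in names(units)) {
    if (is.null(rf_cfg)) {
      d <- if (daily_stat == "mda8") {
        md <- compute_mda8(units[[nm]]$timestamp, units[[nm]][[pollutant]])
        data.frame(date = md$date, value = md$mda8)
      } else {
        aggregate_daily(units[[nm]]$timestamp, units[[nm]][[pollutant]])
      }
      daily[[nm]] <- d[, c("date", "value")]
    } else {
      dm <- deweather_unit(units[[nm]], pollutant, rf_cfg, stride = stride,
                           min_rows = min_rows, daily_stat = daily_stat)
      daily[[nm]] <- dm$daily
      metrics[[nm]] <- dm$metrics
    }
  }

  labels <- sort(unique(calendar$heating_year))
  fits <- list(); weekly_all <- list(); eff_all <- list(); plc <- list()
  factual_annual <- c()
  for (L in labels) {
    gs <- group_heating_start(calendar, treated_ids, L)
    blocks <- weekly_blocks(gs)
    wk <- lapply(daily, function(d)
      aggregate_weekly(d$date, d$value, blocks)$value)
    y1 <- wk$TREATED
    split_periods(cbind(blocks, value = y1))  # validates >= 8 weeks per side
    Y0 <- do.call(rbind, wk[control_ids])
    rownames(Y0) <- control_ids
    prep <- prepare_donor_matrix(Y0)
    if (anyNA(y1)) {
      y1 <- prepare_donor_matrix(rbind(TREATED = y1),
                                 max_missing_frac = 0.10)$Y0[1, ]
    }
    pre_idx <- which(blocks$phase == "pre")
    post_idx <- which(blocks$phase == "post")
    fit <- ascm(y1, prep$Y0, pre_idx, post_idx, lambda_grid = lambda_grid,
                jackknife = jackknife)
    fit$heating_year <- L
    fit$week_start <- blocks$week_start
    fits[[as.character(L)]] <- fit
    eff_all[[as.character(L)]] <- synthetic_difference(
      y1[post_idx], fit, week_start = blocks$week_start[post_idx],
      heating_year = L)
    factual_annual[as.character(L)] <- mean(y1, na.rm = TRUE)
    wtab <- cbind(blocks, heating_year = L,
                  as.data.frame(do.call(cbind, wk)))
    weekly_all[[as.character(L)]] <- wtab
    if (placebo) {
      plc[[as.character(L)]] <- placebo_scan(y1, prep$Y0, pre_idx, post_idx,
                                             lambda_grid = lambda_grid)
    }
  }
  effects <- do.call(rbind, eff_all)
  rownames(effects) <- NULL
  class(effects) <- c("effect_series", "data.frame")
  structure(list(
    fits = fits,
    effects = effects,
    summary = summarize_effects(effects, factual_annual = factual_annual),
    weekly = do.call(rbind, weekly_all),
    metrics = metrics,
    placebo = if (placebo) plc else NULL,
    pollutant = pollutant),
    class = "heating_impact")
}

#' @export
print.heating_impact <- function(x, ...) {
  cat("heating-impact estimate for", x$pollutant, "\n")
  print(x$summary)
  if (!is.null(x$placebo)) {
    for (L in names(x$placebo)) {
      cat(sprintf("  placebo %s: pseudo-p %.4f\n", L,
                  x$placebo[[L]]$pseudo_p))
    }
  }
  invisible(x)
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate (optional) -> deweather -> design -> ascm (+ placebo) ->
#' summarize -> health, writing per-stage artifacts and a manifest into the
#' output directory. Re-running with an identical configuration and seed
#' reproduces identical outputs. Any stage failure aborts with the stage name;
#' partial outputs are retained next to a `FAILED` marker.
#'
#' @param config Named list with fields:
#' \describe{
#'   \item{out_dir}{Output directory (created if needed).}
#'   \item{seed}{Global seed propagated to every stochastic stage.}
#'   \item{simulate}{Either a [panel_config()] (a synthetic panel is generated
#'     and written) or `NULL`, in which case `panel_csv`, `calendar_json` and
#'     `groups_json` paths must be supplied.}
#'   \item{panel_csv,calendar_json,groups_json}{Input paths when not
#'     simulating.}
#'   \item{pollutants}{Character vector (default `"pm25"`).}
#'   \item{rf}{[rf_config()] (its seed is overridden by the global seed);
#'     `NULL` skips deweathering (ASCM on observed data).}
#'   \item{stride}{Deweathering grid spacing (default 3).}
#'   \item{lambda_grid}{Optional ridge grid.}
#'   \item{placebo}{Run placebo scans (default `FALSE`).}
#'   \item{health}{Optional [health_params()]; when present, attributable
#'     deaths are computed for the factual and counterfactual annual means of
#'     the first pollutant.}
#' }
#' @return Invisibly, the manifest list (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  pollutants <- if (is.null(config$pollutants)) "pm25" else config$pollutants
  # echo the configuration (atomic fields only) so every output is
  # re-derivable from the manifest alone
  config_echo <- rapply(config, function(x)
    if (is.atomic(x)) x else NULL, how = "list")
  manifest <- list(package = "synthaq",
                   version = as.character(utils::packageVersion("synthaq")),
                   seed = seed, config = config_echo, stages = list())
  t_all <- Sys.time()
  fail <- function(stage, err) {
    manifest$stages[[stage]] <<- list(status = "FAILED",
                                      error = conditionMessage(err))
    writeLines(stage, file.path(config$out_dir, "FAILED"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(err),
         call. = FALSE)
  }
  stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) fail(name, e))
    manifest$stages[[name]] <<- list(
      status = "COMPLETE",
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    res
  }

  inputs <- stage("simulate", function() {
    if (!is.null(config$simulate)) {
      cfg <- config$simulate
      cfg$seed <- seed
      class(cfg) <- "panel_config"
      sp <- generate_panel(cfg)
      write_panel_csv(sp$panel, file.path(config$out_dir, "panel.csv"))
      write_calendar_json(sp$calendar,
                          file.path(config$out_dir, "calendar.json"))
      write_groups_json(sp$groups, file.path(config$out_dir, "groups.json"))
      list(panel = sp$panel, calendar = sp$calendar, groups = sp$groups)
    } else {
      for (f in c("panel_csv", "calendar_json", "groups_json")) {
        if (is.null(config[[f]]) || !file.exists(config[[f]])) {
          stop("missing input file for '", f, "'")
        }
      }
      list(panel = read_panel_csv(config$panel_csv),
           calendar = read_calendar_json(config$calendar_json),
           groups = read_groups_json(config$groups_json))
    }
  })

  rf_cfg <- if (is.null(config$rf)) {
    rf_config(seed = seed)
  } else if (isFALSE(config$rf)) NULL else {
    x <- config$rf; x$seed <- seed; class(x) <- "rf_config"; x
  }
  stride <- if (is.null(config$stride)) 3L else as.integer(config$stride)

  results <- list()
  # deweather + design + ascm are fused in estimate_heating_impact(); the
  # stages below time and checkpoint each pollutant's artifacts
  for (p in pollutants) {
    hi <- stage(paste0("ascm_", p), function() {
      estimate_heating_impact(inputs$panel, inputs$calendar, inputs$groups,
                              pollutant = p, rf_cfg = rf_cfg,
                              stride = stride,
                              lambda_grid = config$lambda_grid,
                              jackknife = TRUE,
                              placebo = isTRUE(config$placebo),
                              daily_stat = if (is.null(config$daily_stat))
                                "mean" else config$daily_stat)
    })
    results[[p]] <- hi
    write.csv(hi$effects, file.path(config$out_dir,
                                    paste0("effects_", p, ".csv")),
              row.names = FALSE)
    write.csv(hi$weekly, file.path(config$out_dir,
                                   paste0("weekly_", p, ".csv")),
              row.names = FALSE)
    fits_json <- lapply(hi$fits, function(f) {
      list(heating_year = f$heating_year, gamma = as.list(f$gamma),
           lambda = f$lambda, pre_rmse = f$pre_rmse,
           pre_rmse_uniform = f$pre_rmse_uniform,
           counterfactual = f$counterfactual,
           ci_lower = f$ci_lower, ci_upper = f$ci_upper)
    })
    jsonlite::write_json(fits_json,
                         file.path(config$out_dir, paste0("fits_", p, ".json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (length(hi$metrics)) {
      jsonlite::write_json(hi$metrics,
                           file.path(config$out_dir,
                                     paste0("rf_metrics_", p, ".json")),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    if (!is.null(hi$placebo)) {
      pj <- lapply(hi$placebo, function(z)
        list(treated_effect = z$treated_effect,
             placebo_effects = as.list(z$placebo_effects),
             pseudo_p = z$pseudo_p))
      jsonlite::write_json(pj, file.path(config$out_dir,
                                         paste0("placebo_", p, ".json")),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
  }

  stage("summarize", function() {
    sm <- lapply(results, function(hi) {
      list(per_year = hi$summary$per_year,
           mean_annual_effect = hi$summary$mean_annual_effect,
           sd_annual_effect = hi$summary$sd_annual_effect,
           monthly = hi$summary$monthly)
    })
    jsonlite::write_json(sm, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write.csv(results[[1]]$summary$per_year,
              file.path(config$out_dir, "summary_per_year.csv"),
              row.names = FALSE)
    sm
  })

  if (!is.null(config$health)) {
    stage("health", function() {
      hp <- config$health
      py <- results[[1]]$summary$per_year
      rows <- lapply(seq_len(nrow(py)), function(i) {
        fac <- attributable_deaths(py$factual_annual_mean[i], hp)
        cf <- attributable_deaths(py$counterfactual_annual_mean[i], hp)
        list(heating_year = py$heating_year[i],
             af_factual = fac$af, deaths_factual = fac$deaths,
             af_counterfactual = cf$af, deaths_counterfactual = cf$deaths,
             deaths_attributable_to_heating = fac$deaths - cf$deaths)
      })
      jsonlite::write_json(rows, file.path(config$out_dir, "health.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      write.csv(do.call(rbind, lapply(rows, as.data.frame)),
                file.path(config$out_dir, "health.csv"), row.names = FALSE)
      rows
    })
  }

  manifest$seconds_total <- round(as.numeric(difftime(Sys.time(), t_all,
                                                      units = "secs")), 2)
  files <- setdiff(list.files(config$out_dir, full.names = TRUE),
                   file.path(config$out_dir, "manifest.json"))
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(manifest, list(results = results)))
}
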