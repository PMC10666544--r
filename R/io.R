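#' Write / read an hourly panel as CSV
#'
#' Columns: `city_id`, `timestamp` (ISO-8601 UTC hour), pollutants
#' `pm25, so2, no2, co, o3`, meteorology
#' `temp, rh, ws, wd, pressure, blh, tcc, ssr, tp`.
#'
#' @param panel `hourly_panel` data.frame.
#' @param path File path.
#' @return `write_panel_csv`: the path, invisibly. `read_panel_csv`: an
#'   `hourly_panel` data.frame.
#' @export
write_panel_csv <- function(panel, path) {
  out <- panel
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  need <- c("city_id", "timestamp", "pm25", "so2", "no2", "co", "o3",
            MET_VARS)
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("panel CSV lacks columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(df[, c("city_id", "timestamp")])) {
    stop("panel has duplicated (city_id, timestamp) rows")
  }
  conc <- df[, c("pm25", "so2", "no2", "o3")]
  if (any(conc < 0, na.rm = TRUE)) stop("negative concentrations in panel")
  if (any(df$co <= 0, na.rm = TRUE)) stop("CO must be > 0 when present")
  class(df) <- c("hourly_panel", "data.frame")
  df
}

#' Write / read a heating calendar as JSON
#'
#' @param calendar [heating_calendar()].
#' @param path File path.
#' @export
write_calendar_json <- function(calendar, path) {
  rec <- data.frame(city_id = calendar$city_id,
                    heating_year = calendar$heating_year,
                    start = format(calendar$start),
                    end = format(calendar$end))
  jsonlite::write_json(rec, path, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_calendar_json
#' @export
read_calendar_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  heating_calendar(rec$city_id, rec$heating_year,
                   as.Date(rec$start), as.Date(rec$end))
}

#' Write / read a group specification as JSON
#'
#' @param groups [group_spec()].
#' @param path File path.
#' @export
write_groups_json <- function(groups, path) {
  jsonlite::write_json(as.data.frame(groups), path, dataframe = "rows",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_groups_json
#' @export
read_groups_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  group_spec(rec$city_id, rec$group, rec$role, rec$population)
}
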