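#' Lunar New Year dates, 1990-2030
#'
#' Gregorian dates of the Chinese Lunar New Year (first day of the first lunar
#' month) for 1990-2030. The lunar day-of-year feature used in weather
#' normalization is anchored to these dates; a bundled table is exact and
#' avoids an astronomical dependency.
#'
#' @return A data.frame with columns `year` (integer) and `date` (Date).
#' @export
#' @examples
#' head(lunar_new_year_dates())
lunar_new_year_dates <- function() {
  dates <- c(
    "1990-01-27", "1991-02-15", "1992-02-04", "1993-01-23", "1994-02-10",
    "1995-01-31", "1996-02-19", "1997-02-07", "1998-01-28", "1999-02-16",
    "2000-02-05", "2001-01-24", "2002-02-12", "2003-02-01", "2004-01-22",
    "2005-02-09", "2006-01-29", "2007-02-18", "2008-02-07", "2009-01-26",
    "2010-02-14", "2011-02-03", "2012-01-23", "2013-02-10", "2014-01-31",
    "2015-02-19", "2016-02-08", "2017-01-28", "2018-02-16", "2019-02-05",
    "2020-01-25", "2021-02-12", "2022-02-01", "2023-01-22", "2024-02-10",
    "2025-01-29", "2026-02-17", "2027-02-06", "2028-01-26", "2029-02-13",
    "2030-02-03"
  )
  data.frame(year = 1990:2030, date = as.Date(dates))
}

#' Day of the lunar year
#'
#' Number of days elapsed since the most recent Lunar New Year on or before
#' `date`, plus one, so the Lunar New Year itself is day 1. Values range 1-385
#' (a lunar year with a leap month has up to 384 days). Used as a time feature
#' to capture emission changes tied to traditional holidays whose Gregorian
#' date moves from year to year.
#'
#' @param date A `Date` vector.
#' @param lunar_table Table mapping year to Lunar New Year date, as returned by
#'   [lunar_new_year_dates()]. Must cover the year before the earliest `date`
#'   (dates early in a Gregorian year anchor to the previous lunar year).
#' @return Integer vector of lunar days of year.
#' @export
#' @examples
#' lunar_day_of_year(as.Date("2015-02-19")) # Lunar New Year 2015 -> 1
#' lunar_day_of_year(as.Date("2015-03-05")) # Lantern-festival window -> 15
lunar_day_of_year <- function(date, lunar_table = lunar_new_year_dates()) {
  stopifnot(inherits(date, "Date"))
  yrs <- as.integer(format(date, "%Y"))
  need <- sort(unique(c(yrs, yrs - 1L)))
  missing_years <- setdiff(need, lunar_table$year)
  # the previous year is only needed for dates before that year's LNY
  hard_missing <- setdiff(unique(yrs), lunar_table$year)
  if (length(hard_missing) > 0) {
    stop("lunar table does not cover year(s): ",
         paste(hard_missing, collapse = ", "))
  }
  lny_this <- lunar_table$date[match(yrs, lunar_table$year)]
  before <- !is.na(date) & date < lny_this
  if (any(before)) {
    prev_missing <- setdiff(unique(yrs[before] - 1L), lunar_table$year)
    if (length(prev_missing) > 0) {
      stop("lunar table does not cover year(s): ",
           paste(prev_missing, collapse = ", "))
    }
    lny_this[before] <- lunar_table$date[match(yrs[before] - 1L,
                                               lunar_table$year)]
  }
  as.integer(date - lny_this) + 1L
}
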