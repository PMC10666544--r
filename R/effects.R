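#' Synthetic difference (effect) series
#'
#' Factual minus counterfactual on the post-treatment weeks, with Jackknife+
#' bands mapped through the subtraction (effect upper bound uses the
#' counterfactual lower bound and vice versa).
#'
#' @param factual Numeric vector of factual post-week values, or a data.frame
#'   with `week_start` and `value`.
#' @param fit An `ascm_fit` whose `counterfactual` aligns with `factual`.
#' @param week_start Optional Date vector labelling the post weeks.
#' @param heating_year Optional heating-year label attached to the output.
#' @return data.frame of class `effect_series`: `heating_year`, `week_start`,
#'   `effect`, and `ci_lower`/`ci_upper` when the fit carries bands.
#' @export
synthetic_difference <- function(factual, fit, week_start = NULL,
                                 heating_year = NA_integer_) {
  if (is.data.frame(factual)) {
    week_start <- factual$week_start
    factual <- factual$value
  }
  if (length(factual) != length(fit$counterfactual)) {
    stop("factual series and counterfactual are not aligned")
  }
  if (is.null(week_start)) week_start <- as.Date(NA) + seq_along(factual) * 0
  out <- data.frame(heating_year = heating_year, week_start = week_start,
                    effect = factual - fit$counterfactual)
  if (!is.null(fit$ci_lower)) {
    out$ci_lower <- factual - fit$ci_upper
    out$ci_upper <- factual - fit$ci_lower
  }
  class(out) <- c("effect_series", "data.frame")
  out
}

#' Summarize effect series into annual and monthly quantities
#'
#' Per heating year: the heating-period effect (mean over post weeks) and the
#' annual effect, which spreads the post-week effect mass over the full year
#' (`sum(effects) * 7 / 365`), the factual and counterfactual annual means,
#' and the relative contribution
#' (`annual_effect / factual_annual_mean * 100`). Across years: mean and SD
#' of the annual effects, and calendar-month means pooled over years with SD.
#'
#' @param effects `effect_series` rows covering one or more heating years
#'   (post weeks only).
#' @param factual_annual Named numeric vector: factual annual mean
#'   concentration per heating year (names are labels). Needed for relative
#'   contributions; optional.
#' @param convention `"annual"` (default: effect mass over 365 days) or
#'   `"heating_period"` (mean over post weeks reported as the annual figure).
#' @return list of class `effect_summary`: `per_year` data.frame
#'   (`heating_year`, `heating_period_effect`, `annual_effect`,
#'   `factual_annual_mean`, `counterfactual_annual_mean`,
#'   `relative_contribution`), `mean_annual_effect`, `sd_annual_effect`,
#'   `monthly` data.frame (`month`, `mean`, `sd`, `n`).
#' @export
summarize_effects <- function(effects, factual_annual = NULL,
                              convention = c("annual", "heating_period")) {
  convention <- match.arg(convention)
  stopifnot(all(c("heating_year", "week_start", "effect") %in% names(effects)))
  yrs <- sort(unique(effects$heating_year))
  per_year <- do.call(rbind, lapply(yrs, function(L) {
    e <- effects$effect[effects$heating_year == L]
    hp <- mean(e, na.rm = TRUE)
    ann <- if (convention == "annual") {
      sum(e, na.rm = TRUE) * 7 / 365
    } else hp
    fa <- if (!is.null(factual_annual)) factual_annual[[as.character(L)]]
          else NA_real_
    data.frame(heating_year = L, heating_period_effect = hp,
               annual_effect = ann,
               factual_annual_mean = fa,
               counterfactual_annual_mean = fa - ann,
               relative_contribution = if (!is.na(fa) && fa != 0)
                 100 * ann / fa else NA_real_)
  }))
  mon <- as.integer(format(effects$week_start, "%m"))
  monthly <- do.call(rbind, lapply(sort(unique(mon)), function(m) {
    e <- effects$effect[mon == m]
    data.frame(month = m, mean = mean(e, na.rm = TRUE),
               sd = stats::sd(e[!is.na(e)]), n = sum(!is.na(e)))
  }))
  structure(list(per_year = per_year,
                 mean_annual_effect = mean(per_year$annual_effect),
                 sd_annual_effect = stats::sd(per_year$annual_effect),
                 monthly = monthly,
                 convention = convention),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat("effect summary (", x$convention, " convention)\n", sep = "")
  print(x$per_year, row.names = FALSE, digits = 4)
  cat(sprintf("multi-year annual effect: %.2f +/- %.2f\n",
              x$mean_annual_effect,
              ifelse(is.na(x$sd_annual_effect), 0, x$sd_annual_effect)))
  invisible(x)
}

#' Linear trend rate of annual values
#'
#' Ordinary least squares of annual values on calendar year; reports the
#' slope (units per year), intercept and R-squared from the same fit.
#'
#' @param year Integer vector of calendar years (>= 3 distinct).
#' @param value Annual values.
#' @return list of class `trend_fit`: `slope`, `intercept`, `r2`.
#' @export
#' @examples
#' trend_rate(2015:2021, 100 - 5 * (0:6)) # slope -5, r2 = 1
trend_rate <- function(year, value) {
  ok <- !is.na(year) & !is.na(value)
  year <- year[ok]; value <- value[ok]
  if (length(unique(year)) < 3) stop("need >= 3 years for a trend rate")
  fit <- stats::lm(value ~ year)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((value - mean(value))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = r2),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend: %.3f per year (R^2 = %.3f)\n", x$slope, x$r2))
  invisible(x)
}

#' Absolute and percent change between two values
#'
#' Exact arithmetic; rounding happens only at presentation.
#'
#' @param a Baseline value (nonzero).
#' @param b Endpoint value.
#' @return list: `change` (`b - a`), `percent` (`100 * (b - a) / a`).
#' @export
#' @examples
#' percent_change(14.4, 3.2) # -11.2, -77.8%
percent_change <- function(a, b) {
  if (any(a == 0)) stop("baseline value must be nonzero")
  list(change = b - a, percent = 100 * (b - a) / a)
}
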