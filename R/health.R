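#' Exposure-response parameters for PM2.5 health burden
#'
#' Default curve is log-linear with a counterfactual threshold:
#' `RR(c) = exp(beta * max(0, c - c0))`. Alternative curves (e.g. tabulated
#' integrated exposure-response functions) plug in as `rr_fun(c, params)`.
#'
#' @param beta Log relative risk per ug/m3 (>= 0).
#' @param c0 Counterfactual threshold concentration in ug/m3 (>= 0) below
#'   which no excess risk is attributed.
#' @param baseline_deaths Annual baseline deaths in the exposed population
#'   (>= 0).
#' @param rr_fun Optional function `(c, params) -> RR` overriding the default
#'   curve; must return values >= 1.
#' @return Object of class `health_params`.
#' @export
health_params <- function(beta = 0.005, c0 = 5, baseline_deaths = 0,
                          rr_fun = NULL) {
  stopifnot(beta >= 0, c0 >= 0, baseline_deaths >= 0,
            is.null(rr_fun) || is.function(rr_fun))
  structure(list(beta = beta, c0 = c0, baseline_deaths = baseline_deaths,
                 rr_fun = rr_fun),
            class = "health_params")
}

#' Relative risk at a concentration
#'
#' @param c Concentration(s) in ug/m3 (>= 0).
#' @param params A [health_params()].
#' @return Relative risk >= 1 (vectorized).
#' @export
#' @examples
#' relative_risk(45, health_params(beta = 0.005, c0 = 5)) # exp(0.2)
relative_risk <- function(c, params) {
  stopifnot(inherits(params, "health_params"))
  if (any(c < 0, na.rm = TRUE)) stop("concentration must be >= 0")
  if (!is.null(params$rr_fun)) {
    rr <- params$rr_fun(c, params)
    if (any(rr < 1, na.rm = TRUE)) stop("rr_fun returned RR < 1")
    return(rr)
  }
  exp(params$beta * pmax(0, c - params$c0))
}

#' Attributable fraction and premature deaths for a concentration scenario
#'
#' `af = 1 - 1/RR(c)`; `deaths = af * baseline_deaths`.
#'
#' @param c_scenario Annual mean PM2.5 concentration (ug/m3).
#' @param params A [health_params()].
#' @return list of class `health_impact`: `concentration`, `rr`, `af`,
#'   `deaths`.
#' @export
attributable_deaths <- function(c_scenario, params) {
  rr <- relative_risk(c_scenario, params)
  af <- 1 - 1 / rr
  structure(list(concentration = c_scenario, rr = rr, af = af,
                 deaths = af * params$baseline_deaths),
            class = "health_impact")
}

#' @export
print.health_impact <- function(x, ...) {
  cat(sprintf(
    "health impact: c = %.1f ug/m3, RR = %.4f, AF = %.4f, deaths = %.0f\n",
    x$concentration, x$rr, x$af, x$deaths))
  invisible(x)
}

#' Avoided deaths relative to a baseline year
#'
#' Exact difference `deaths_baseline - deaths_current`; positive when the
#' current year has fewer attributable deaths than the baseline.
#'
#' @param deaths_baseline,deaths_current Attributable deaths (>= 0).
#' @return Persons per year.
#' @export
#' @examples
#' avoided_deaths(169016, 145460) # 23556
avoided_deaths <- function(deaths_baseline, deaths_current) {
  stopifnot(all(deaths_baseline >= 0), all(deaths_current >= 0))
  deaths_baseline - deaths_current
}
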