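---
title: "Weather-normalized synthetic control estimation of heating impacts on air quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weather-normalized synthetic control estimation of heating impacts on air quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(synthaq)
```

## The estimation problem

Municipal winter heating injects a seasonal pulse of primary emissions into
northern Chinese cities every year from the October/November switch-on until
30 April. Estimating its causal contribution to ambient concentrations is hard
for two reasons. First, meteorology confounds everything: winters have shallow
boundary layers and weak dispersion, so concentrations rise in winter even at
constant emissions. Second, there is no off-treatment observation for a
heated city: heating arrives every year, so before/after contrasts within a
city do not identify the effect, and north/south difference-in-differences
fails because the two regions do not satisfy parallel trends.

`synthaq` implements a two-stage design that addresses both problems:

1. **Weather normalization ("deweathering").** A random forest is trained per
   city and pollutant on meteorological covariates (temperature, relative
   humidity, wind speed and direction, pressure, boundary-layer height, total
   cloud cover, surface net solar radiation, precipitation) plus time
   covariates (Unix time as a trend proxy, day of year, lunar day of year,
   day of week, hour of day). The deweathered concentration at an hour is the
   mean of the forest's predictions when the meteorological block is replaced
   by states resampled from the observation record, with the time covariates
   held fixed.
2. **Ridge-augmented synthetic control (ASCM).** Weekly deweathered series of
   a treated unit are compared against a counterfactual built from
   non-heating (southern) control cities. Simplex weights `gamma` minimize
   the pre-treatment (1 May to switch-on) discrepancy; a cross-sectional
   ridge outcome model then corrects the weighted average for residual
   pre-treatment imbalance. The synthetic difference (factual minus
   counterfactual) over the heating period is the causal heating impact.

The estimator for one treated unit and heating year is

```
counterfactual(s) = gamma' Y0_post[, s] + (y1_pre - Y0_pre' gamma)' eta_s
eta_s = solve(X'X + lambda I, X' y_s),   X = Y0_pre centered by control means
```

with `gamma >= 0`, `sum(gamma) = 1` (plus a `1e-8` ridge tie-break for
uniqueness), and `lambda` chosen by leave-one-control-out cross-validation of
the augmented prediction on a 10-point grid scaled to `mean(diag(X'X))`
(spanning `1e-3` to `1e3` times it). Fits are per heating year, so each
year's pre period contains only non-heating weeks.

Uncertainty is quantified two ways. *Jackknife+* refits the estimator leaving
each control out, and combines the leave-one-out counterfactuals with a
per-refit residual scale into pointwise 95% prediction bands using the
finite-sample `floor(alpha(n+1))` / `ceiling((1-alpha)(n+1))` order-statistic
convention (indices clamped to `[1, n]`, which keeps the bands finite for
small donor pools at some cost in conservatism). The residual scale is
deliberately conformal: each pre week is predicted from weights refitted
without it, and the scale is the `ceiling((1-alpha)(n_pre+1))`-th order
statistic of the absolute out-of-sample residuals. Two cheaper definitions
were examined in coverage simulations and rejected — the in-sample pre-period
RMSE is optimistic (the weights are fitted on those very weeks; measured
pointwise coverage 0.72 at nominal 0.95 on weekly panels) and the
cross-validated RMSE still misses the tail factor (0.82); the conformal
quantile reaches 0.98, conservative as expected from the clamped order
statistics. *In-place placebo tests*
refit every control city as a pseudo-treated unit; the rank of the treated
unit's absolute heating-period mean effect among the placebos gives
`pseudo_p = (1 + #{|placebo| >= |treated|}) / (n_placebo + 1)`.

## Design choices that were genuinely open

**Resampling window.** The deweathering literature is split on whether
meteorological states should be resampled from the whole record or from a
seasonal window. The difference matters more than it looks. A regression
forest given both seasonal met covariates and calendar covariates spreads the
*emission* seasonality across both: boundary-layer height or temperature can
isolate "winter" in one split whereas the circular day-of-year needs two, so
part of the seasonal emission signal (including any winter step intervention)
is encoded in meteorological splits. Full-record resampling then strips that
share from the deweathered series — in our parameter-recovery experiments it
removed 40–50% of a known winter step, robustly across `mtry`, raw/log
targets and met-effect functional forms, and even when the target contained
no meteorological signal at all. `synthaq` therefore defaults to resampling
from a ±21-day circular day-of-year window pooled across years
(`rf_config(resample_window_days = 21)`): synoptic variability is averaged
out while each site's seasonal meteorological climate is preserved, and
injected interventions are recovered essentially in full. The trade-off is
explicit: windowed deweathering leaves seasonal *climatological* differences
between cities in the series (the synthetic control stage absorbs level and
shape differences through the weights and the ridge correction), whereas
full-record resampling (`resample_window_days = Inf`) removes them at the
price of attenuating emission seasonality. The window half-width is a
compromise between pool size (about 1000 valid hours per day-of-year per
two-year record) and seasonal drift within the window.

**Target scale.** The forest is trained on raw concentrations by default;
`rf_config(log_target = TRUE)` trains on logs and back-transforms. In our
experiments the choice did not change recovery behaviour; raw scale keeps the
bias metric interpretable in concentration units.

**Train/test split.** A seeded uniform random 70/30 row split, matching the
cited workflow; `chronological_split = TRUE` is available for stress testing
(random splits flatter held-out metrics when observations are
autocorrelated, which is why the held-out correlation contract, r > 0.7, is
deliberately undemanding).

**Weeks are anchored to the heating start**, not ISO weeks, so the treatment
boundary coincides with a week boundary and no week mixes pre and post hours.
Intervals are half-open `[start, start + 7)`; the week containing the
switch-on date is the first post week. Partial terminal blocks are dropped.

**Aggregation validity thresholds** follow common regulatory practice: a
daily mean needs 18 of 24 hours, a weekly mean 4 of 7 days, an 8-hour ozone
window 6 of 8 hours, and an MDA8 day 18 of 24 valid windows. When deweathered
values are evaluated on a reduced hourly grid (below), the daily threshold
scales to 75% of the grid's per-day count.

**Gas-phase unit conversion** for total oxidant uses the 25 °C / 1013 hPa
reference state (NO2: 1.88, O3: 1.96 µg m⁻³ per ppb), the convention of
China's post-2018 ambient standards.

**Missing donor data.** A control city missing more than 10% of weeks in a
fit window is dropped from the donor pool; shorter interior gaps (at most two
consecutive weeks) are linearly interpolated.

**No intercept in the weight stage.** Level differences between the treated
unit and the donor pool are handled by the ridge stage's centering, not by an
intercept in the simplex fit, mirroring the reference ridge-ASCM
formulation.

## The synthetic panel generator

`generate_panel()` emulates the structure of city-level hourly monitoring
panels so the full pipeline can be validated by parameter recovery:

- **Meteorology**: seasonal sinusoids with AR(1) noise (lag-1 coefficient
  0.95, a decorrelation time of about a day, typical synoptic persistence);
  winter temperature minimum, winter-shallow boundary layer with a daytime
  convective cycle, cloud-modulated solar radiation, occasional
  precipitation.
- **Concentrations**: positive baseline = linear trend + seasonal + weekly +
  diel harmonics + a Lunar-New-Year emission bump, plus an additive centered
  nonlinear meteorological component (shallow boundary layer, weak wind and
  high humidity raise primary pollutants; sunlight and temperature raise
  ozone), all times multiplicative lognormal noise with mean one
  (`noise_sd` is the sdlog, default 0.25). The heating effect is an additive
  step in concentration units during heating dates in treated cities
  (`alternative_fraction` of the step in partially heated cities), so the
  injected delta is directly comparable to a synthetic difference.
- **Bookkeeping**: every component is recorded per hour and sums exactly to
  the observed value; `true_weekly_effect()` converts the recorded heating
  component into the population-weighted weekly truth.

Default study conditions: 20 control, 8 treated and 3 alternative cities,
two complete heating years (May 2015 – April 2017), a 10 µg m⁻³ PM2.5 step,
trend −3 µg m⁻³ yr⁻¹, common 8 November switch-on (a jitter knob exists), and
lognormally distributed populations around 3 million. What the generator does
*not* emulate: atmospheric chemistry (no secondary-aerosol response),
inter-city transport, spatially correlated meteorology, instrument artefacts,
and north-south climate contrasts (all cities share one climate). Passing
recovery tests therefore demonstrates internal consistency of the estimator
under known conditions, not robustness to every real-data pathology — in
particular, the choice of resampling window cannot be adjudicated by these
panels alone (both windows yield unbiased recovery when control and treated
climates match; they differ when climates diverge).

## Problem sizes and numerical choices

- The recovery study deweathers 21 units (the population-weighted treated
  group plus 20 controls) with `n_resample = 100` draws, evaluating
  deweathered values every 6 hours (0:00, 6:00, 12:00, 18:00 UTC). Evenly
  spaced diel sampling is unbiased for daily means — harmonics of the diel
  cycle not divisible by the grid average to zero — and cuts forest
  prediction volume fourfold. The weekly series entering the ASCM are
  unchanged in expectation.
- Monte-Carlo studies of interval coverage (200 replicates) and placebo
  calibration (50 replicates each) run on weekly-resolution panels (10–12
  controls, 20–26 pre weeks, 10–24 post weeks) generated directly at the
  weekly scale; the hourly machinery adds nothing to those questions.
- The simplex QP is solved by a primal active-set method with an exact KKT
  verification (relative tolerance 1e-6); ill-conditioned donor ensembles
  (near-identical controls) fall back to an accelerated projected-gradient
  polish. The solver is deterministic, so ASCM outputs are bit-reproducible.
- Ridge systems are solved in closed form; a singular system at
  `lambda = 0` falls back to the smallest positive grid value with a
  warning.
- Negative deweathered values are clipped to zero at reporting only, never
  inside the resampling average.

## Known limitations

- Deweathering attribution is identified only up to the overlap between
  meteorological and calendar covariates; the windowed default trades
  removal of climatological differences for fidelity of emission signals, as
  discussed above.
- Jackknife+ bands assume exchangeable controls; with heterogeneous donor
  pools the clamped order statistics make the bands conservative rather than
  exact.
- The annual effect convention spreads the heating-period effect mass over
  365 days (`sum(post-week effects) × 7 / 365`), attributing each heating
  season wholly to the year in which it starts; a `heating_period`
  convention is available where the mean over post weeks is wanted instead.
- The health module's default exposure-response is a thresholded log-linear
  relative risk, `RR(c) = exp(beta · max(0, c − c0))`, with attributable
  fraction `1 − 1/RR` — a deliberately simple default; integrated
  exposure-response curves can be plugged in as tabulated functions, and
  baseline mortality is a required user input.
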