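# synthaq

Causal attribution of air-quality interventions from city-level pollutant
panels, built for the question of how much municipal **winter heating** adds
to ambient PM2.5, SO2, CO and ozone in northern Chinese cities — and how much
clean-heating policy has taken away.

The package couples two stages:

1. **Random-forest weather normalization** ("deweathering"). Hourly
   concentrations are modelled on nine meteorological covariates (temperature,
   RH, wind speed/direction, pressure, boundary-layer height, cloud cover,
   solar radiation, precipitation) and five time covariates (Unix-time trend,
   day of year, lunar day of year, day of week, hour of day; forest of 300
   trees, minimum node size 5, seeded 70/30 train/test split). The
   deweathered value at an hour averages `n_resample` predictions with the
   meteorological block replaced by states drawn from a seasonal window of
   the observation record, time covariates held fixed.
2. **Ridge-augmented synthetic control (ASCM)**. Weekly deweathered series of
   a treated unit are matched to a convex combination of non-heating control
   cities over the pre-treatment period (1 May to the heating switch-on):

   `min || y1_pre − Y0_pre' γ ||²  s.t.  γ ≥ 0, Σγ = 1`

   then corrected by a cross-sectional ridge outcome model,
   `counterfactual(s) = γ'Y0_post[,s] + (y1_pre − Y0_pre'γ)' η_s` with
   `η_s = (X̃'X̃ + λI)⁻¹ X̃' y_s`, λ by leave-one-control-out CV. The synthetic
   difference (factual − counterfactual) over heating weeks is the causal
   heating impact, with Jackknife+ pointwise 95% bands and in-place placebo
   inference (`pseudo_p = (1 + #{|placebo| ≥ |treated|}) / (n + 1)`).

Downstream helpers turn effect series into heating-period and annual effects,
monthly profiles, relative contributions, trend rates, percent changes, and
attributable health burden (`AF = 1 − 1/RR`) under a pluggable
exposure-response.

A synthetic hourly panel generator (`generate_panel()`) with an exactly
recorded trend/seasonal/meteorology/noise/heating decomposition supports
end-to-end parameter-recovery validation; see the methods vignette
(`vignettes/methods.Rmd`) for the model, assumptions, and design choices.

## Worked example

```r
library(synthaq)

cfg <- panel_config(n_control_cities = 6, n_treated_cities = 3,
                    n_alternative_cities = 0, seed = 11)
sp  <- generate_panel(cfg)              # 2 heating years, PM2.5 step = 10
rf  <- rf_config(n_resample = 30, seed = 11)
hi  <- estimate_heating_impact(sp$panel, sp$calendar, sp$groups,
                               pollutant = "pm25", rf_cfg = rf, stride = 6,
                               jackknife = FALSE)
print(hi)
```

```
heating-impact estimate for pm25
effect summary (annual convention)
 heating_year heating_period_effect annual_effect factual_annual_mean
         2015                 9.973         4.781               49.12
         2016                 9.640         4.437               47.50
 counterfactual_annual_mean relative_contribution
                      44.34                 9.734
                      43.06                 9.341
multi-year annual effect: 4.61 +/- 0.24
```

The injected heating step is 10 µg m⁻³ during the Nov–Apr heating period;
the pipeline recovers heating-period mean effects of 9.97 and 9.64 µg m⁻³
for the two heating years. The *annual* effect spreads the heating-period
effect mass over 365 days (`sum of weekly effects × 7 / 365`), and the
relative contribution divides it by the factual annual mean — here heating
contributes ~4.6 µg m⁻³ (~9.5%) of annual PM2.5, from a ~9.8 µg m⁻³
heating-season enhancement.

Report arithmetic helpers work on printed number pairs:

```r
percent_change(14.3, 8.4)   # $change -5.9   $percent -41.3
avoided_deaths(169016, 145460)  # 23556
```

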