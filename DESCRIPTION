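Package: synthaq
Title: Weather-Normalized Synthetic Control Analysis of Air Quality
    Interventions
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Causal attribution of air-quality interventions from city-level
    pollutant panels. Couples random-forest weather normalization of hourly
    pollutant concentrations (meteorological resampling, "deweathering") with
    ridge-augmented synthetic control estimation of intervention effects,
    Jackknife+ pointwise prediction intervals, in-place placebo inference,
    effect summaries (weekly, monthly, annual synthetic differences and
    relative contributions) and attributable health burden under a pluggable
    exposure-response. Includes a synthetic hourly panel generator with a
    known component decomposition for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
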