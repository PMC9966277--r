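# pifsim

Macro-simulation of cancer cases preventable by population-level changes in
dietary exposure, built around the potential impact fraction (PIF). The
package is aimed at epidemiologists and health-impact modellers who want to
project, over a multi-decade horizon, how many age- and sex-stratified
colorectal cancer cases a reduction or elimination of red and processed
meat intake could prevent — and at anyone who needs the same machinery for
another continuous exposure with a log-linear dose-response.

## The model in brief

Individual relative risk is log-linear in daily intake: for a factor with
relative risk RR_u per reference unit of u grams/day (defaults: 1.16 per
50 g processed meat, 1.12 per 100 g red meat),

    RR_i = exp(M_i · ln(RR_u) / u)

An intervention scenario maps each intake M_i to a counterfactual M_i*
(serving-wise reduction floored at zero, or elimination). The PIF of a
stratum follows the RR-shift method,

    PIF = 1 − Σ_i w_i RR_i(M_i*) / Σ_i w_i RR_i(M_i)

and is phased in through a latency period (LAT, default 1 year, no risk
change) and a lag period (LAG, default 9 years, gradual log-scale risk
transition). Expected cases per year, sex, and 5-year age band — incidence
rate × population / 100,000 — are multiplied with the stratum-year PIF and
accumulated into annual and cumulative prevented-case series.

Because the survey microdata, registry incidence, and official population
forecasts behind such analyses are typically not redistributable, the
package ships calibrated synthetic generators: a zero-inflatable lognormal
exposure survey fitted to published intake quantiles, an
exponential-in-age incidence surface, and a cohort-drift population
projection. File readers accept real inputs in the same simple CSV shapes.

## Worked example

```r
library(pifsim)

# half a 100 g reference unit at RR 1.16
individual_rr(50, risk_factor("processed_meat", 1.16, 100))
#> [1] 1.077032

# full default run: synthetic inputs, six scenarios, lags 9/5/15, 2020-2050
res <- run_pipeline(default_run_config(seed = 1), verbose = FALSE)
s <- res$summary
s[s$lag_years == 9 & s$sex == "both", c("scenario", "prevented", "pct_prevented")]
#>   scenario              prevented pct_prevented
#> 1 processed_elimination    298421          10.6
#> 2 processed_minus_1         71020           2.5
#> 3 processed_minus_2        124607           4.4
#> 4 red_elimination          101747           3.6
#> 5 red_minus_1               27902           1.0
#> 6 red_minus_2               51952           1.8

cat(format_summary_table(s[s$lag_years == 9 & s$sex == "male", ]), sep = "\n")
#> Lag time: 9 years
#>   male (expected cases: 1,553,794)
#>     scenario                                #        %
#>     processed_elimination             208,775     13.4
#>     processed_minus_1                  40,587      2.6
#>     processed_minus_2                  74,777      4.8
#>     red_elimination                    70,054      4.5
#>     red_minus_1                        15,654      1.0
#>     red_minus_2                        30,410      2.0
```

Reading the output: about 2.8 million colorectal cancer cases are expected
over 2020–2050 from the synthetic inputs (1.55 M men, 1.26 M women);
eliminating processed meat intake would prevent roughly 10.6% of them, a
one-serving-per-day reduction about 2.5%, with the per-year series ramping
up over the first decade (latency 1 + lag 9) and tracking demography
afterwards. Counts from synthetic inputs are order-of-magnitude analogues
of a national projection, not registry estimates; supply real survey,
incidence, and population CSVs through the `file:` blocks of the run
configuration to reproduce a registry-scale analysis.

`run_pipeline(cfg, output_dir = "run1")` additionally writes
`projection.csv`, `summary.csv`, `summary.txt`, `annual_series.csv`,
`survey.csv`, and a `manifest.json` that makes the run byte-for-byte
reproducible. A thin command-line wrapper with verbs `generate-data`,
`simulate`, `report`, and `fixtures` lives at `inst/cli/pifsim`.

See `vignettes/meat-intake-simulation.Rmd` for the full account of the
model, the synthetic-data calibration, and the package's design choices.

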