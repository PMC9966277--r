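---
title: "Modelling preventable colorectal cancer cases from meat-intake interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling preventable colorectal cancer cases from meat-intake interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pifsim)
```

## The model

`pifsim` is a macro-simulation: it never simulates individual disease
events. Instead it combines three population-level ingredients —

1. an **exposure distribution**: individual daily intakes of red and
   processed meat (grams/day) by sex and 5-year age group;
2. a **dose-response model** translating intake into relative risk (RR) of
   colorectal cancer; and
3. **expected case numbers** from age- and sex-specific incidence rates held
   constant over time, multiplied with projected population counts —

into potential impact fractions (PIFs) and prevented case counts under
counterfactual intake scenarios.

### Dose-response

Risk is log-linear in intake: for a factor with relative risk $RR_u$ per
reference unit of $u$ grams/day,

$$RR_i = \exp\!\left(M_i \,\frac{\ln RR_u}{u}\right),$$

where $M_i$ is individual $i$'s intake. The defaults are the WCRF/IARC
continuous estimates, $RR_u = 1.16$ per $u = 50$ g/day of processed meat and
$RR_u = 1.12$ per $u = 100$ g/day of red meat. Log-linearity means risk is
exactly 1 at zero intake and multiplicative in intake increments; joint
red + processed risk is taken as the product of the two factor RRs, since
independent log-linear terms combine multiplicatively. RRs are treated as
age- and sex-independent; age and sex enter only through the intake
distributions and the incidence rates.

### The RR-shift potential impact fraction

A scenario maps each individual's intake $M_i$ to a counterfactual
$M_i^\ast$ (a fixed grams/day reduction floored at zero, or elimination).
The PIF in a stratum is

$$\mathrm{PIF} = 1 - \frac{\sum_i w_i\,RR_i(M_i^\ast)}{\sum_i w_i\,RR_i(M_i)},$$

with sampling weights $w_i$ (default 1). With $M_i^\ast \equiv 0$ this is
the population attributable fraction. Because the PIF averages over the
full individual-level RR distribution rather than evaluating the RR at the
mean intake, it respects the convexity of the exponential dose-response:
for any non-degenerate intake distribution the distribution-based PIF
exceeds the point-mass PIF at the same mean.

### Latency, lag, and the yearly ramp

Risk does not respond instantly to an intake change. For an intervention
starting in year $y_0$ with latency $LAT$ (no risk change) and lag $LAG$
(gradual change), the completed fraction of the transition in year $y$ is

$$f(y) = \mathrm{clamp}\!\left(\frac{y - y_0 - LAT}{LAG},\, 0,\, 1\right),$$

evaluated at integer years. Each individual's time-dependent RR
interpolates between baseline and counterfactual **on the log-RR scale**:
$RR_i(y) = RR_i^{1-f(y)}\,(RR_i^\ast)^{f(y)}$. Under the log-linear
dose-response this is identical to shrinking the *effective intake*
linearly from $M_i$ to $M_i^\ast$, which is the natural scale on which the
exposure change itself unfolds. A consequence worth knowing: the PIF is
then slightly convex, not linear, in $f$, so lag-sensitivity contrasts
computed from linear ramp sums are approximate upper bounds (the measured
mean lag-5/lag-15 contrast comes out near 9% rather than the 10% a linear
ramp-sum argument suggests).

Defaults are $LAT = 1$ year and $LAG = 9$ years (sensitivity variants 5 and
15), start year 2020, horizon 2020–2050: annual preventable numbers ramp up
over the first decade and then track demography only.

An optional `phase_in_years` switch additionally phases the intake change
itself in linearly (e.g. over 5 years from the start year) and composes it
with the LAT/LAG ramp. The default is 0 — the counterfactual intake applies
at once and only LAT/LAG delays the risk response — because the
ten-year ramp-up produced by LAT 1 + LAG 9 alone is the behaviour the
simulation is designed to exhibit; the switch exists for exploring how an
explicit adoption period would compound the delay.

### From PIFs to cases

Expected cases per year, sex, and age group are
$\text{rate} \times \text{count} / 10^5$; prevented cases are expected
cases times the stratum-year PIF, accumulated over the horizon. Counts stay
real-valued internally; rounding (whole cases, one-decimal percentages from
unrounded totals) happens only at report time. Percentages are reported per
sex, with a combined-sex row for headline figures. Strata with no exposure
data — the under-18 band — contribute expected cases with an explicit PIF
of 0; a PIF that is simply *missing* for a productive stratum is an error
rather than a silent zero.

## Scenarios

Six default scenarios: for each meat type, reduction by one serving per
day, by two servings per day, and elimination. One serving-equivalent is
75 g per week, i.e. 10.7 g/day averaged over the week (`serving_g_day()`).
Reductions are applied uniformly per individual in grams/day with a floor
at zero — the simplest individual-level rule that realises the intended
mean shift for everyone consuming more than the reduction. Elimination is
idempotent; two successive one-serving reductions equal one two-serving
reduction wherever the floor does not bind.

## The synthetic data generators

The study population the pipeline is calibrated to cannot be
redistributed, so the package generates statistically analogous inputs.

**Exposure survey.** Published summary statistics of German adult meat
intake (`intake_reference_summaries()`: quartiles, means, and 99th
percentiles by sex and by age band) are turned into zero-inflatable
lognormal fits by matching the printed median and third quartile:
$\mu = \ln(\text{median})$, $\sigma = \ln(q_3/\text{median})/z_{0.75}$ in
the zero-mass-free case. Median and Q3 are the most stable printed
statistics; the mean and the 99th percentile are held out as diagnostics
(the male processed-meat fit implies a mean of 62.3 g/day against a printed
61, and a $p_{99}$/median ratio of 5.7 against a printed 5.1). The printed
table gives sex margins and age margins separately; the default synthesis
fits each age band and shifts its log-location by the sex-to-overall ratio
of printed *means* — medians are uninformative here because red-meat
medians are identical across sexes while the means differ — which is an
approximation, documented as such. Printed means are treated as crude
means, although the source labels them age-standardized without naming the
standard. The 80+ band reuses the 75–79 fit (the survey stops at 79);
under-18 intake is not modelled. Within an individual, red and processed
intake are coupled by a Gaussian copula with Spearman correlation 0.3 by
default (the normal-score correlation is $2\sin(\pi\rho_s/6)$): the source
tables are silent on this coupling, and a moderate positive value reflects
that meat-heavy diets are heavy in both types. Zero inflation defaults to 0
— printed minima of 0 with positive first quartiles imply a small zero
mass that the fit supports (conditional quantile levels) but that the
default omits.

**Incidence.** A deterministic exponential-in-age rate surface: the rate
doubles every 10 years of age (band midpoints), with a male:female ratio
of 1.3 and a female rate of 39 per 100,000 person-years at ages 50–54.
These defaults were calibrated once so that, with the default population,
roughly two million expected cases accrue over a 31-year horizon — the
order of magnitude of a national colorectal-cancer projection — and were
not tuned further.

**Population.** A cohort-drift projection: each year, `count / width`
persons age out of every closed band into the next, a constant entry cohort
(375,000 per sex-year) enters the youngest band, and each band is thinned
by an annual survival factor (1 for closed bands, 0.80 for the open 80+
band, i.e. a mean residence of five years past 80). Flows conserve persons
exactly up to entry and survival losses. A `constant_population()` helper
repeats fixed counts instead, which is the right setting for lag
sensitivity analyses where only the temporal dynamics should vary.

**What the generators do *not* emulate.** Survey sampling design and
weights, secular intake trends, sex-by-age intake interactions beyond the
mean shift, registry-grade incidence detail, and migration-driven
population waves. Passing tests therefore demonstrate that the *method* is
implemented correctly and behaves as the model predicts on data with the
assumed structure — not that the absolute case counts match any national
registry projection. Absolute counts from synthetic inputs are
order-of-magnitude analogues only.

## Numerical choices

- PIF and case arithmetic run in double precision end to end; cumulative
  sums are plain running sums (tests require cumulative = sum of annual to
  1e-6 relative).
- Floating-point test comparisons use 1e-12 tolerance for closed-form
  identities and looser, explicitly stated tolerances for stochastic
  recovery checks.
- The ramp is evaluated at integer year starts; clamping handles years
  before the intervention and after the transition, so no special-casing of
  the horizon edges is needed.
- Degenerate inputs fail loudly: empty strata, all-zero weights, negative
  intakes (with the offending record index), mismatched stratum keys, and
  scenario targets without an intake column are all rejected with messages
  naming the offender.
- `fit_lognormal_from_quantiles` accepts `q3 = median` (a point mass,
  $\sigma = 0$), used in tests to pin the generator's plumbing.

## Typical problem sizes

The default configuration uses 400 records per sex-age stratum (26 adult
strata, 10,400 records), six scenarios, and three lag variants over 31
years — about two seconds of compute. Calibration checks in the test suite
draw up to 100,000 records for quantile-recovery assertions. These sizes
give sampling noise well inside the tolerances asserted; users reproducing
registry-scale analyses should substitute their own survey, incidence, and
population files via the `file:` blocks of the run configuration.

## Worked example

```{r example, eval = FALSE}
cfg <- default_run_config(seed = 1)
res <- run_pipeline(cfg, output_dir = "run1")
res$summary[res$summary$lag_years == 9 & res$summary$sex == "both", ]
cat(format_summary_table(res$summary), sep = "\n")
```

The run writes `projection.csv` (the full year × sex × age × scenario
table), `summary.csv`/`summary.txt` (per-sex scenario totals with `#` and
`%` columns per lag variant), `annual_series.csv` (annual and cumulative
prevented cases, sexes combined), the generated `survey.csv`, and a
`manifest.json` echoing the configuration and versions, which suffices to
reproduce every output byte for byte.

## Known limitations

- No uncertainty propagation: RRs enter as point estimates and the output
  carries no intervals.
- No dietary substitution: intake is reduced *ceteris paribus*; compensating
  consumption of other foods is out of scope.
- No age-at-exposure effect modification; the same RR applies at all ages.
- Incidence rates are frozen at their baseline level, so screening effects
  or cohort trends in risk are not represented.
- The serving-equivalent (10.7 g/day) and all scenario deltas are
  deterministic; behavioural heterogeneity in uptake is not modelled.
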