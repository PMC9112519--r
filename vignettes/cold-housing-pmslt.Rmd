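---
title: "Modelling cardiovascular gains from eradicating indoor cold: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cardiovascular gains from eradicating indoor cold: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldpmslt)
```

## The question and the model

Cold indoor environments raise systolic blood pressure (SBP), and raised SBP
raises the incidence of ischemic heart disease and stroke. `coldpmslt`
quantifies the cardiovascular health gain of a "magic wand" intervention
that permanently lifts all cold homes from an assumed average indoor
temperature of 16 °C to 20 °C, for a closed base-year (2016) population of
three Australian states, expressed as health-adjusted life years (HALYs).

The machinery is a **proportional multistate lifetable (pMSLT)**:

* a **main lifetable** ages each of the 42 sex × 5-year-age-band cohorts in
  annual cycles under all-cause mortality, accumulating person-years by the
  mid-cycle approximation and weighting each person-year down by the
  all-cause morbidity proportion (YLD per capita) to give HALYs;
* three **disease lifetables** (ischemic heart disease, ischemic stroke,
  haemorrhagic stroke) run in parallel and independently for every cohort as
  three-state processes — healthy, prevalent, dead-from-disease — driven by
  incidence and case fatality, with remission fixed at zero (chronic-disease
  convention; the inputs carry no remission column);
* the model is run twice, business-as-usual (BAU) and intervention, and the
  two arms are linked by **population impact fractions (PIFs)** that scale
  intervention-arm incidence down. Each cycle the between-arm differences in
  disease mortality (case fatality × prevalence) and in disease YLD rates
  are summed across diseases and absorbed by the main lifetable as a hazard
  increment and a morbidity increment. Nothing else differs between arms, so
  a zero-effect scenario reproduces BAU to machine precision (this is a
  test).

Cohorts are represented at their mid-band age, use the rate band containing
their current attained age (half-open bands; the 100–104 band carries
forward to the terminal age), and are extinguished at age 110.

## From temperature to incidence

The trial anchoring the exposure effect contrasted rooms at 22 °C vs 12 °C
and found SBP 5.8 mmHg lower when warm (awake measurements). We treat the
effect as linear in temperature — 0.58 mmHg per °C — so a 4 °C lift yields
roughly a 2 mmHg waking-hours elevation attributable to cold housing.
Exposure is not year-round: occupants face indoor cold for between one sixth
and one half of the year (cold half of the year, waking hours, at-home
time), modelled as a Beta(10.5, 22) fraction (median 0.319, 2.5th–97.5th
percentiles 0.176–0.490). The annualised SBP shift removed by the
intervention is

```
delta = time_fraction × (t_target − t_cold) × sbp_effect / effect_contrast
```

about 0.75 mmHg at the distribution's mean. We use the mean (not the
median) of the exposure-time distribution for the central deterministic run,
since the reported central estimate plays the role of an expectation.

The shift converts to a PIF with the unexposed as reference and the exposed
carrying relative risk `exp(beta × delta)`, where `beta = ln(RR per 10
mmHg)/10` is the log-linear risk slope of the band containing the cohort's
attained age:

```
PIF = pi (e^{beta delta} − 1) / (pi e^{beta delta} + 1 − pi)
```

Because the risk is log-linear, this two-group shift formula is *exactly*
equal to the distributional formulation that integrates the risk over the
full normal SBP distribution (a moment-generating-function identity — the
normal's MGF factor cancels between numerator and denominator). The package
carries both: `pif_shift()` as the engine default, `pif_distributional()` by
adaptive quadrature as an independent cross-check, and the test suite holds
them to 1e-10 of each other over randomised parameters. The reference SBP
level (TMREL) cancels for the same reason and never needs to be specified.

Two deliberate zeros: ages below 15 have no recorded SBP and get PIF 0, and
the PIF applies to incidence only — case fatality is unchanged by the
intervention.

One open choice the formulas expose: whether the recorded SBP distribution
of the exposed already contains the cold-induced elevation. The shift
formulation is agnostic; the distributional variant defaults to "elevation
sits on top of the recorded mean" (`sbp_baseline = "elevated"`), which is
the reading under which the two formulations coincide, and offers
`"recorded"` (giving `pi (1 − e^{−beta delta})`) as the alternative.

## Annual cycle mathematics

Within a cycle all rates are constant hazards, so the disease system

```
dS/dt = −i S,   dC/dt = i S − f C,   dD/dt = f C
```

has the exact matrix-exponential solution used by `step_disease()`:
`S' = S e^{−i}`, `C' = C e^{−f} + i S (e^{−i} − e^{−f})/(f − i)`, with the
analytic limit `C' = C e^{−f} + i S e^{−i}` taken when `|f − i| ≤ 1e-9`
(the difference quotient is numerically safe above that). Dead mass is
updated as the complement, so `S + C + D` is conserved to better than
1e-12 per cycle (tested), and the whole cycle is held to 1e-6 against an
independent stiff ODE integrator for rates up to 1.

Initial disease prevalence is seeded from the inputs' implied steady state
`C0 = i/(i+f)` of the alive mass. The base-year table prints incidence,
case fatality and disability but not prevalence counts, so this is the only
self-contained seed; an optional `prev_<disease>` column overrides it where
observed prevalence is available. The steady-state seed overstates true
prevalence at ages where incidence has risen steeply (the coherence report
flags the three male mid-age strata where summed implied disease mortality
marginally exceeds all-cause mortality), which mainly affects the first
years of the projection.

The main lifetable treats rates as hazards (`l' = l e^{−(m + dm)}`), not
probabilities, takes mid-cycle person-years `L = (l + l')/2`, and anchors
discounting at 2016 with the base year undiscounted:
`value/(1+r)^(year−2016)`. Reporting windows are half-open: the 20-year
horizon covers 2016–2035 inclusive. All-cause mortality is held at 2016
levels — no trend is stated for it — and a configurable trend
(`acmr_trend`) exists for sensitivity analysis. Annual percentage changes
(APC) on disease incidence and case fatality are accepted per disease but
default to 0, because the values the original analysis estimated from
1990–2016 trends are not published; this is the single largest known source
of divergence from the published headline gains (declining CVD trends
shrink far-future gains and concentrate the total in early years). The
morbidity proportion is clamped to [0, 1] with a warning — removing disease
YLD can never create negative morbidity.

## Input tables and units

Input files follow the published table's conventions: incidence, disability
and mortality rates per 100,000 persons, case fatality per prevalent
case-year, prevalence in percent; `load_cohort_inputs()` converts to
per-person rates (× 1e-5) on load and `write_cohort_inputs()` inverts it
exactly (round-trip tested). The packaged `table2_2016.csv` carries the 42
base-year strata (total population 15,560,018); within-block repeats of the
printed prevalence values are stored exactly as printed, with no
re-smoothing.

The SBP→disease relative risks belong in a user-supplied CSV
(`disease, age_group, rr_per_10mmhg[, rr_lo, rr_hi]`). The packaged
`synthetic_sbp_rr_by_age.csv` is a **constructed stand-in, not the original
source table**: a log-linear-in-age schedule anchored at RR 1.60 per
10 mmHg for ischemic heart disease at ages 55–59, with stroke steeper than
heart disease, haemorrhagic steeper than ischemic, attenuation with age,
and a floor of 1.05 at the oldest ages — the standard shape of pooled
cohort and GBD risk curves. Conclusions that depend on the exact risk
schedule (notably the lifetime headline gain) should be read as
conditional on it; substituting the original supplementary schedule is a
one-line change.

## Uncertainty propagation

`run_monte_carlo()` redraws, per iteration: the exposure-time fraction
(Beta(10.5, 22)); the trial SBP effect (Normal(5.8, 1.76), the sd recovered
from its 95% CI); age-specific exposure prevalence (Normal, sd = 2 × a
binomial survey standard error with an effective sample size of ~214 per
band — the survey's 4,500 households spread over 21 bands — with an
exchangeable cross-age correlation of 0.1574 induced by a shared
standard-normal factor, i.e. a one-factor Gaussian copula); lognormal
incidence multipliers with 5% sd; normal disability-rate multipliers with
10% sd; and lognormal relative-risk multipliers within the published CIs.
Disease-input multipliers are drawn once per disease and applied to both
sexes and all ages — the between-sex correlation of 1.0 is stated by the
source, and the cross-age structure (not stated) is taken as the
whole-schedule perturbation typical of spreadsheet-era probabilistic
sensitivity analysis. Invalid prevalence draws are clipped to [0, 1];
other invalid draws (negative effect sizes or multipliers) are rejected and
redrawn so their distributions keep shape away from the boundary; both
counts are reported. Intervals are empirical 2.5th/97.5th percentiles, the
central estimate is reported both as the central-parameter run and as the
draw mean (the source does not say which convention it used), and
everything is reproducible by seed (tested bitwise).

## The synthetic-data generator

`generate_inputs()` emulates what the real tables look like statistically:
Gompertz all-cause mortality (band values are exact band-average hazards,
so the band schedule's survival matches the continuous curve at band
edges), log-linear-in-age disease incidence/case fatality/disability,
morbidity rising with age under a cap, SBP drifting up with age, and
exposure prevalence declining with age. It does **not** emulate survey
design, sampling weights, cohort effects, or between-disease correlation —
so passing tests on synthetic data demonstrate engine correctness, not
real-world calibration. Two closed-form harnesses ride on it:

* with disease and morbidity switched off, the engine's life expectancy for
  the youngest cohort must match the generated band schedule's exact
  survival integral to 0.1% (the residual is the trapezoidal person-year
  approximation, about 0.02%); the 5-year band discretisation itself sits
  about 0.24% below the continuous Gompertz integral, which is bounded
  separately — a property of banded inputs, not of the engine;
* `known_truth_experiment()` collapses the model to one cohort with flat
  rates, where the PIF is a single analytic constant and the whole two-arm
  lifetable is a short scalar recursion, recomputed independently of the
  engine and matched to 1e-6 relative error.

## Problem sizes and runtime

The full model is 42 cohorts × 108 annual cycles × 3 diseases × 2 arms and
runs in ~0.1 s; the packaged analyses and checks use 200 Monte Carlo
iterations (~25 s), which bounds percentile noise at a level well inside
the qualitative statements made about the intervals. The original analysis
used 2,000 iterations; `scenario_config(iterations = 2000)` reproduces that
setting directly.

## Known limitations

* Only the SBP→CVD pathway is modelled; respiratory and mental-health
  effects of cold housing, temperature–mortality dose-response curves, and
  heat are out of scope, so gains are conservative by construction.
* Diseases are independent parallel lifetables; no competing-risk
  interaction or acute/chronic phase split.
* Closed cohorts: no births, migration, or future entry into cold housing;
  exposure prevalence per cohort is frozen at its 2016 value.
* The steady-state prevalence seed and the zero APC defaults are the two
  assumptions that most limit quantitative agreement with the published
  headline values; both are overridable inputs.
* The packaged risk schedule is synthetic (above); the packaged comparator
  league table carries only the three published comparator values.
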