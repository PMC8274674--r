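---
title: "Methods: a capacity-constrained system dynamics model of a regional mental health system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a capacity-constrained system dynamics model of a regional mental health system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhsd)
```

## The model

`mhsd` simulates psychological distress, service pathways and suicidal
behaviour in a regional population of about half a million people as a
continuous-time stock-and-flow (system dynamics) model, integrated at a
fixed step of 1/16 of a week (0.4375 days) from 2011 to 2030. Time is
measured in weeks, a model year is exactly 52 weeks (832 steps), and all
rates are per week. Five sectors interact:

* **Population.** Four age groups (0–14, 15–24, 25–64, 65+) with a constant
  birth inflow, constant net migration inflows, per-capita mortality
  hazards, and aging flows whose rates are the reciprocals of the band
  widths. The initial total is 502,524 persons.
* **Psychological distress.** Adults (15+) are partitioned into three
  Kessler-10 bands: low (K10 10–15), moderate (16–21) and high/very high
  (22–50). Upward transitions (onset) are first-order per-capita hazards
  scaled by the social-determinant pressure multiplier; downward transitions
  are spontaneous remission plus service-delivered recovery, which moves
  people down exactly one band. Demographic flows (youth aging in, adult
  migration, adult mortality) are mirrored onto the bands so that the bands
  always partition the adult population exactly; migration enters in
  proportion to the current band shares (migrants are assumed similar to
  residents), and aging from 0–14 enters the low band.
* **Social determinants.** Unemployment, homelessness and substance misuse
  are level stocks with constant inflows and first-order exits; domestic
  violence exposure and adverse early-life exposure are static indices; the
  sense-of-community index is an exogenous time profile. The *pressure
  multiplier* is a Cobb–Douglas power product
  $\prod_d (L_d/L_d^{ref})^{w_d}\,(S^{ref}/S)^{w_{soc}}$ over adverse levels
  $L_d$ and the sense-of-community index $S$; it equals 1 when everything
  sits at its baseline reference, rises with any adverse determinant and
  falls with connectedness. Pressure multiplies distress onset directly and
  enters the attempt and disengagement rates through sector exponents
  (`gamma_attempt`, `gamma_diseng`), so one index drives all three couplings
  with separately tunable strength.
* **Service system.** Seven channels: general practice, psychiatrists +
  allied professionals, community mental health (CMHC), emergency
  department, psychiatric inpatient, outpatient, and online services. Each
  has a capacity stock (services/week) growing linearly by a yearly
  increment, a waiting queue, a disengagement hazard, and a per-service
  recovery probability. Throughput is `min(demand + waiting, capacity)`;
  excess joins the queue, which drains proportionally alongside new demand.
  People waiting remain in their distress band (the queue is a tally of
  unmet demand, not a holding stock), so person conservation is exact.
  GP consultations of high-distress patients are referred onward to
  specialised care with probability `p_ref_high`; moderate-band GP patients
  may be referred to online services. Multi-session channels (specialist,
  CMHC, outpatient) deliver their recovery only to treatment completers:
  the completion fraction is `mu / (mu + disengagement)`, which is how a
  lower disengagement rate raises effectiveness even when capacity is the
  binding constraint.
* **Suicidal behaviour.** Attempts arise predominantly from the high band
  (`att_high`, with a small moderate-band rate), scaled by pressure.
  Self-harm hospitalizations are `hosp_frac` × attempts (default 1: the
  hospitalization series is the attempt proxy). Suicide deaths are
  `case_fatality` × attempts and are removed from both the high band and
  the adult population. MH-related ED presentations are a crisis share of
  attempts plus a per-capita rate from *untreated* high distress, where
  untreated means the high stock minus `care_protect_weeks` (default 1) of
  in-care status per high-band service delivered that week. Three
  cumulative counters (self-harm hospitalizations, suicide deaths, ED
  presentations) reset at the 2021.0 epoch so that the 2021–2030 forecast
  window is a single counter read at the end of the horizon.

### Integration

The engine is a generic fixed-step integrator over a declarative model
graph (stocks, flows, auxiliaries, counters, time-profiled shocks). The
default scheme is explicit Euler with *uniform proportional rationing*:
when the total outflow of a stock over one step would exceed its content,
all outflows from that stock are scaled by a common factor so the stock is
exactly exhausted, and the scaled rate is applied at both ends of each
flow, preserving mass. Euler is the conventional default for this class of
model and interacts correctly with the rationing rule. A classical
fourth-order Runge–Kutta scheme (`scheme = "rk4"`) is available for smooth
regimes: it does not ration (stage states are clamped at zero instead) and
is the right choice when accuracy against a smooth reference solution
matters. At the default step the Euler solution of a pure decay
`dS/dt = -0.1 S` per week deviates from the closed form by ~1.6% after a
year — the expected first-order error `k^2 T \, dt/2` — while RK4 is exact
to ~10 digits; cumulative counters of the full model change by well under
1% when the step is halved, which is the practically relevant accuracy
statement for the reported outcomes.

### Interventions and uptake

Four built-in scenarios mirror the study design: business as usual;
a 20% increase in the yearly capacity growth of GP, specialist and CMHC
services; standard telehealth; and technology-enabled care coordination.
An intervention acts through nine multipliers (recovery, referral to
specialised care, disengagement, AOD referral, substance-use relapse,
employment initiation, exiting homelessness, specialised capacity, online
referral) and through its capacity-increment schedule. Coverage follows the
*maximum rate per service* `u_max`: uptake ramps linearly from the 2021
start over one year (a package choice; the ramp time is a spec field) and
each multiplier enters as the population-mix blend
`1 + u(t) (m - 1)` of covered and uncovered services. The referral
multiplier applies only to high/very-high-distress GP consultations;
moderate-band referrals are untouched. Capacity increments switch from the
baseline schedule to the scenario schedule at the start year, so the
2011–2020 history is identical across scenarios and comparisons are clean.
The standard-telehealth referral multiplier defaults to 1.00 — telehealth
extends existing services online without changing referral pathways — and
the tabulated outlier value (10.00) can be set explicitly by the user; the
telehealth column's other non-unit values (recovery 1.09, disengagement
0.76, relapse 0.93, capacity 1.10) are kept as given.

### Pandemic conditions

Post-pandemic conditions install three exogenous profiles starting at
2020.25: (i) the unemployment inflow is multiplied by a shock factor
(15 at onset) decaying exponentially at 0.05/week; (ii) the youth job-loss
ratio (5) amplifies the unemployment level inside the pressure term by
`1 + (ratio - 1) × youth share × shock profile` — the distress bands are
not age-stratified, so the youth effect is expressed through the pressure
channel; (iii) the sense-of-community index ramps from 9.61 to 8.24 over
one year, holds for the two-year period of social disconnection, then
ramps back over the same time (the symmetric return is a package choice;
the source tables specify only the decline). Pre-pandemic conditions are
an exact no-op: all profiles stay at their baseline constants and the
trajectory is bit-identical to a run with no condition set applied.

## Parameters and calibration

All ~90 parameters carry units, bounds, a sector tag and a description
(`params_table()`), and serialize to a flat, self-documenting YAML schema.
Almost none of the functional forms or rate constants of the original
regional model are in the public record, so the defaults here were chosen
once, by magnitude reasoning at the regional scale (e.g. specialist
capacity of order 100k services/year for a 500k population, unemployment
pool ~30k, K10 high/very-high prevalence declining from ~19% of adults in
2011), and then adjusted so the business-as-usual run passes near the five
published baseline outputs. They are the calibration starting values, not
estimates about the original model.

`calibrate()` minimises a weighted sum of squared *relative* errors over a
bounded box of free parameters (default: the ~10 rates that most directly
shape the baseline anchors, each bounded at ±30% of its default). The
optimizer is derivative-free bounded Nelder–Mead on a logit-rescaled box —
the objective is cheap but mildly nonsmooth because of the `min()` capacity
constraints — started from Latin-hypercube points screened at a coarse step
(1/4 week) and refined at the reporting step (1/16 week); the best point
ever evaluated at the reporting step is returned, so a fit is never worse
than its starting values. The convergence flag is true iff every target's
relative error is within its tolerance (1% for the forecast anchors, 5% for
historic series rows). With the default noisy synthetic historic series the
flag is honestly `FALSE` — yearly suicide counts of ~100 carry ~10% Poisson
noise that no parameter vector can fit within 5% — while all five anchors
are matched well within 1%.

A target with observed value zero contributes its absolute error (on its
own unit scale) instead of a relative one. Degenerate inputs are handled
explicitly: zero free parameters evaluates the objective once; a non-finite
objective aborts naming the parameter set.

## Sensitivity analysis

`run_sensitivity()` draws `n` (default 100) parameter sets by Latin
hypercube sampling from independent uniform bands of ±20% around the
scenario's direct-effect parameters (the uptake maximum, every multiplier
differing from 1, and any capacity increment differing from the baseline
schedule). Multipliers below 1 are perturbed by ±20% *of their value* and
clamped positive. Each replicate re-runs the intervention and is compared
with the business-as-usual baseline; the baseline does not depend on the
sampled parameters and is computed once. Each comparison metric is
summarised by its value at the nominal parameters and the empirical
2.5th/97.5th percentiles (type-7 quantiles) across replicates — reported as
a "95% interval", which is a parameter-uncertainty band and explicitly
*not* a confidence interval. With two replicates the type-7 endpoints
interpolate 2.5% of the way in from the extremes rather than returning the
order statistics exactly; this follows from the quantile definition and is
asserted as such in the tests. Replicates that fail to integrate are
excluded with a warning; more than 5% failures aborts.

## Synthetic historic data

No regional dataset is distributed with the package. `generate_historic()`
emulates the *statistical shape* of the five validation series (distress
prevalence, psychiatric hospitalizations, MH-related ED presentations,
self-harm hospitalizations, suicide deaths; yearly, 2011–2017): linear
trends with Poisson noise on counts and Gaussian noise on the logit scale
for prevalence, bit-identical under a fixed seed, with the generating truth
attached for recovery tests. Default trend levels are a linear fit to the
default model's own business-as-usual yearly indicators (about 1,330
self-harm hospitalizations and 103 suicide deaths per year), so the
synthetic series is internally consistent with the forecast anchors. What
it deliberately does not emulate: seasonality, reporting artefacts, census
revisions, autocorrelated shocks. Tests that pass against these series
therefore demonstrate the machinery (calibration, recovery, validation
plumbing), not agreement with real regional surveillance data.

## Numerical and design choices

* Stocks representing people are continuous; counts are rounded only at
  reporting.
* Queue composition in the mixed-band GP channel is approximated by the
  current demand mix.
* Prevalence is high-band stock over the modelled adult (15+) population,
  reported in percent.
* The problem sizes used by the test suite are chosen for tight feedback:
  most property tests integrate at dt = 1/2 or 1/4 week, where the Euler
  error is still far below the tolerances being asserted; accuracy-critical
  checks (anchors, scenario orderings, convergence) run at the reporting
  step of 1/16 week. Calibration screens at dt = 1/4 and refines at 1/16.
* Scenario comparisons in this implementation reproduce the qualitative
  structure of the study — technology-enabled care coordination dominates
  standard telehealth, which dominates accelerated capacity growth, under
  both condition sets, with monotone gains in uptake — but the *magnitudes*
  of the scenario effects depend on the unpublished equation set and
  calibration data of the original model and are not reproduction targets
  here; only the business-as-usual baseline is calibrated to published
  values.

## Known limitations

* Distress is not age-stratified, so youth-specific effects act through
  aggregate channels.
* The ED appears both as a service channel and as an outcome counter; the
  outcome counter is kept independent of the treatment-pathway bookkeeping
  (crisis share of attempts + untreated high distress) so that changing the
  service wiring does not silently redefine the outcome.
* Disengagement from a capacity-saturated queue does not change delivered
  services (capacity binds either way); its outcome effect flows through
  treatment completion.
* The determinant pathway weights are package assumptions, config-swappable
  and documented in `params_table()`; they are not estimates from the
  original study's evidence synthesis.
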