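# mhsd — system dynamics modelling of a regional mental health system

`mhsd` is an R package for simulating how psychological distress, social
determinants of mental health, capacity-constrained service pathways and
suicidal behaviour interact in a regional population (~500,000 people), and
for asking *what-if* questions about the service system: what happens to
self-harm hospitalizations, suicide deaths, mental-health-related emergency
department (ED) presentations and the prevalence of high psychological
distress if service capacity grows faster, if existing services move online
(standard telehealth), or if digital technology is used to coordinate
multidisciplinary care — under ordinary conditions and under a
pandemic-recession shock?

It is aimed at health-system modellers and mental-health services
researchers who want a transparent, fully scriptable stock-and-flow model
with calibration and sensitivity analysis built in.

## The model in brief

The population is partitioned into Kessler-10 distress bands — low (10–15),
moderate (16–21), high/very high (22–50) — over four age groups. Band
transitions are first-order hazards: onset is scaled by a social-determinant
*pressure* multiplier

> pressure = ∏ᵈ (Lᵈ / Lᵈʳᵉᶠ)^wᵈ · (Sʳᵉᶠ / S)^wˢᵒᶜ,

a Cobb–Douglas product over unemployment, homelessness, substance misuse,
domestic violence and early-life exposure levels Lᵈ and the
sense-of-community index S, equal to 1 at baseline. Recovery flows come from
seven service channels (GP, psychiatrist + allied, community mental health,
ED, inpatient, outpatient, online), each with capacity *C(t)* in
services/week growing linearly per year, throughput
min(demand + waiting, C), waiting queues and disengagement. Suicide
attempts arise from the high band (rate `att_high` × pressure^γ); self-harm
hospitalizations are the attempt proxy, deaths are a case-fatality fraction,
and ED presentations combine a crisis share of attempts with a rate from
untreated high distress. Everything is integrated by explicit Euler at
dt = 1/16 week (0.4375 days) from 2011 to 2030, with cumulative outcome
counters reset at 2021.

Interventions act through uptake-blended multipliers
`1 + u(t)·(m − 1)` on recovery, referral, disengagement, relapse,
employment, housing, capacity and online-referral rates, plus their own
capacity-growth schedules. Four scenarios are built in: business as usual,
+20% capacity growth, standard telehealth, technology-enabled care
coordination. Pre/post-pandemic condition sets add an exponentially decaying
unemployment shock, a youth job-loss amplification and a sense-of-community
dip (9.61 → 8.24 and back).

## Worked example

```r
library(mhsd)

cfg <- sf_config(2011, 2030, dt = 1/16)
baseline <- outcome_summary(
  mhsd_simulate(scenario = "business_as_usual", covid = "pre", config = cfg))
print(baseline)
#> Cumulative outcomes, 2021.0-2030.0:
#>   self-harm hospitalizations       12289
#>   suicide deaths                     954
#>   MH-related ED presentations      81270
#>   high-distress prevalence    17.63% (2021) -> 15.62% (2030)

coord <- outcome_summary(
  mhsd_simulate(scenario = "tech_enabled_coordination", covid = "pre", config = cfg))
compare_outcomes(baseline, coord)
#> Outcome comparison, 2021.0-2030.0 (reduction vs baseline):
#>   self-harm hospitalizations    9.34%  (1147 prevented)
#>   suicide deaths                9.34%  (89 prevented)
#>   MH-related ED presentations   9.76%  (7933 prevented)
#>   high-distress prevalence      2.59 percentage points
```

The baseline block is the model's 2021–2030 forecast under business as
usual: about 12,300 self-harm hospitalizations, 950 suicide deaths and
81,000 MH-related ED presentations, with high-distress prevalence declining
from 17.6% of adults in 2021 to 15.6% in 2030 as service capacity grows.
The comparison block shows the effect of technology-enabled care
coordination at 70% maximum uptake: roughly 9% fewer self-harm
hospitalizations and suicide deaths and a 2.6-percentage-point lower 2030
prevalence. Scenario effects are ordered — coordination beats standard
telehealth, which beats accelerated capacity growth — under both
pre- and post-pandemic conditions.

Other entry points:

```r
fit <- calibrate(seed = 1)                   # fit free parameters to the baseline anchors
summary(fit)
res <- run_sensitivity(spec = builtin_scenarios()$tech_enabled_coordination)
print(res)                                   # 100-draw LHS, 95% percentile intervals
h <- generate_historic(seed = 1)             # synthetic 2011-2017 indicator series
```

A thin command-line wrapper with subcommands `run`, `report`, `calibrate`,
`sensitivity`, `sweep-uptake` and `make-synthetic` ships in
`inst/cli/mhsd.R`.

## Package layout

- `R/engine.R` — generic fixed-step stock-and-flow integrator (Euler with
  proportional outflow rationing; optional RK4), model validation,
  trajectories.
- `R/model.R`, `R/params.R` — the regional model and its documented
  parameter schema.
- `R/scenarios.R` — intervention scenarios, uptake blending, pandemic
  condition sets, outcome comparison.
- `R/sensitivity.R` — Latin hypercube designs and percentile intervals.
- `R/calibration.R` — multi-start bounded calibration against target
  anchors and series.
- `R/synthetic.R` — synthetic historic indicator series and packaged
  calibration targets.
- `R/cli.R`, `inst/cli/mhsd.R` — run orchestration and the command line.
- `vignettes/mhsd-methods.Rmd` — the full methods account: assumptions,
  functional forms, parameter choices, numerical decisions, limitations.
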