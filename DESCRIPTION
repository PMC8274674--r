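Package: mhsd
Title: System Dynamics Modelling of a Regional Mental Health System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A capacity-constrained stock-and-flow simulator of psychological
    distress, social determinants of mental health, service pathways, and
    suicidal behaviour in a regional population, together with a scenario
    engine for service-system interventions (business as usual, accelerated
    capacity growth, standard telehealth, technology-enabled care
    coordination) under pre- and post-pandemic socioeconomic conditions.
    Includes a generic fixed-step stock-and-flow integrator, Latin hypercube
    sensitivity analysis with percentile interval summaries, constrained
    multi-start calibration of free model parameters against target series
    and cumulative outcomes, and a synthetic-data generator for historic
    indicator series.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    lhs,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
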