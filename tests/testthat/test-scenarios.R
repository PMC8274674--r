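test_that("built-in scenarios carry the intervention parameter table", {
  sc <- builtin_scenarios()
  expect_setequal(names(sc), c("business_as_usual", "capacity_growth_20",
                               "standard_telehealth", "tech_enabled_coordination"))
  bau <- sc$business_as_usual
  expect_identical(bau$u_max, 0)
  expect_true(all(bau$multipliers == 1))
  expect_equal(c(bau$inc_gp, bau$inc_psy, bau$inc_cmhc), c(125.85, 216.31, 0))

  cap <- sc$capacity_growth_20
  expect_equal(c(cap$inc_gp, cap$inc_psy, cap$inc_cmhc), c(151.02, 259.57, 75.14))
  expect_true(all(cap$multipliers == 1))

  tel <- sc$standard_telehealth
  expect_equal(tel$u_max, 0.70)
  expect_equal(unname(tel$multipliers[c("m_rec", "m_ref", "m_dis", "m_rel", "m_cap")]),
               c(1.09, 1.00, 0.76, 0.93, 1.10))

  tec <- sc$tech_enabled_coordination
  expect_equal(tec$u_max, 0.70)
  expect_equal(unname(tec$multipliers),
               c(1.18, 1.27, 0.52, 1.10, 0.87, 1.10, 1.10, 1.10, 1.10))
  expect_equal(c(tec$inc_gp, tec$inc_psy, tec$inc_cmhc), c(125.85, 216.31, 0))
})

test_that("scenario constructors reject invalid specifications", {
  expect_error(scenario_spec("x", u_max = 1.2), "u_max")
  expect_error(scenario_spec("x", m_rec = 0), "positive")
})

test_that("uptake is zero before start, ramps linearly, then saturates", {
  spec <- scenario_spec("x", u_max = 0.7, start_year = 2021, ramp_years = 1)
  expect_identical(uptake(2015, spec), 0)
  expect_equal(uptake(2022, spec), 0.7)
  expect_equal(uptake(2025, spec), 0.7)
  spec8 <- scenario_spec("x", u_max = 0.8, start_year = 2021, ramp_years = 1)
  expect_equal(uptake(2021.5, spec8), 0.4)
})

test_that("effective multipliers blend covered and uncovered services", {
  expect_identical(effective_multiplier(5, 0), 1)
  expect_identical(effective_multiplier(0.2, 0), 1)
  expect_equal(effective_multiplier(1.18, 1), 1.18)
  expect_equal(effective_multiplier(0.52, 0.7), 0.664)
  # the referral blend applied to a 0.30 base GP referral probability
  expect_equal(0.30 * effective_multiplier(1.27, 0.7), 0.3567)
})

test_that("business as usual under pre-pandemic conditions is a bit-identical no-op", {
  cfg <- cfg_fast(2011, 2023)
  plain <- mhsd_simulate(config = cfg)
  scen <- mhsd_simulate(scenario = "business_as_usual", covid = "pre", config = cfg)
  expect_identical(scen$stocks, plain$stocks)
  expect_identical(scen$counters, plain$counters)
})

test_that("the referral effect is restricted to the high-distress band", {
  cfg <- sf_config(2021, 2022, dt = 1 / 4, record_every = 1L)
  ref_only <- scenario_spec("ref_only", u_max = 0.7, m_ref = 1.27,
                            start_year = 2021, ramp_years = 0)
  tr_bau <- mhsd_simulate(scenario = "business_as_usual", covid = "pre", config = cfg)
  tr_ref <- mhsd_simulate(scenario = ref_only, covid = "pre", config = cfg)
  i <- 3L  # shortly after the step change, state drift still negligible
  expect_gt(tr_ref$flows[i, "queue_join_psy"], tr_bau$flows[i, "queue_join_psy"])
  expect_equal(tr_ref$flows[i, "queue_join_onl"], tr_bau$flows[i, "queue_join_onl"],
               tolerance = 1e-4)
})

test_that("outcome comparisons implement the reduction arithmetic", {
  b <- make_summary(12274, 953, 81263, 17.60, 15.60)
  expect_equal(unlist(compare_outcomes(b, b)[1:7], use.names = FALSE),
               rep(0, 7))
  s <- make_summary(11430, 900, 76000, 17.60, 14.00)
  cmp <- compare_outcomes(b, s)
  expect_equal(cmp$prevented_self_harm, 844)
  expect_equal(cmp$pct_reduction_self_harm, 100 * 844 / 12274)
  expect_equal(round(cmp$pct_reduction_self_harm, 3), 6.876)
  expect_equal(cmp$pp_reduction_prevalence, 1.60)
  z <- make_summary(0, 0, 0, 10, 10)
  w <- capture_warnings(cmp0 <- compare_outcomes(z, z))
  expect_length(w, 3)  # one per zero-baseline counter
  expect_match(w, "zero", all = TRUE)
  expect_true(is.na(cmp0$pct_reduction_self_harm))
  expect_error(compare_outcomes(b, make_summary(1, 1, 1, 1, 1, window = c(2021, 2025))),
               "window")
})

test_that("pandemic conditions worsen every business-as-usual counter", {
  cfg <- cfg_fast()
  pre <- mhsd_simulate(scenario = "business_as_usual", covid = "pre", config = cfg)
  post <- mhsd_simulate(scenario = "business_as_usual", covid = "post", config = cfg)
  expect_true(all(post$counters > pre$counters))
  # and the sense-of-community profile reaches its target a year after onset
  cv <- covid_conditions("post")
  p <- apply_scenario(mhsd_params(), builtin_scenarios()$business_as_usual, cv)
  shocks <- attr(p, "shocks")
  soc <- shocks[[which(vapply(shocks, `[[`, "", "name") == "soc_index")]]
  expect_equal(soc$profile(cv$shock_onset + 1.0, NULL), 8.24)
  expect_equal(soc$profile(cv$shock_onset + 0.5, NULL), (9.61 + 8.24) / 2)
  expect_equal(soc$profile(2015, NULL), 9.61)
})

test_that("scenario effects are ordered: coordination > telehealth > capacity > none", {
  cfg <- cfg_fast()
  sc <- builtin_scenarios()
  base <- outcome_summary(mhsd_simulate(scenario = sc$business_as_usual,
                                        covid = "pre", config = cfg))
  red <- sapply(sc[-1], function(sp) {
    cmp <- compare_outcomes(base, outcome_summary(
      mhsd_simulate(scenario = sp, covid = "pre", config = cfg)))
    c(cmp$pct_reduction_self_harm, cmp$pct_reduction_suicide, cmp$pct_reduction_ed)
  })
  for (k in 1:3) {
    expect_gt(red[k, "tech_enabled_coordination"], red[k, "standard_telehealth"])
    expect_gt(red[k, "standard_telehealth"], red[k, "capacity_growth_20"])
    expect_gt(red[k, "capacity_growth_20"], 0)
  }
})
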