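test_that("determinant pressure is a reference-anchored power product", {
  expect_identical(determinant_pressure(c(1, 2, 3), c(1, 2, 3), c(0.5, 1, 2)), 1)
  expect_equal(determinant_pressure(2, 1, 0.5), sqrt(2))
  # sense-of-community drop from 9.61 to 8.24 with unit weight
  expect_equal(determinant_pressure(numeric(), numeric(), numeric(),
                                    soc_index = 8.24, soc_ref = 9.61, w_soc = 1),
               9.61 / 8.24, tolerance = 1e-12)
  expect_error(determinant_pressure(-1, 1, 1), "positive")
  expect_error(determinant_pressure(1, 0, 1), "positive")
})

test_that("pressure is monotone: up in adverse levels, down in connectedness", {
  base <- determinant_pressure(c(10, 5), c(10, 5), c(0.3, 0.2),
                               soc_index = 9.61, soc_ref = 9.61, w_soc = 0.6)
  worse <- determinant_pressure(c(12, 5), c(10, 5), c(0.3, 0.2),
                                soc_index = 9.61, soc_ref = 9.61, w_soc = 0.6)
  disconnected <- determinant_pressure(c(10, 5), c(10, 5), c(0.3, 0.2),
                                       soc_index = 8.24, soc_ref = 9.61, w_soc = 0.6)
  expect_gt(worse, base)
  expect_gt(disconnected, base)
})

test_that("service throughput clamps at capacity and drains the queue", {
  expect_equal(service_throughput(10, 0, 20),
               c(served = 10, newly_waiting = 0))
  expect_equal(service_throughput(30, 0, 20),
               c(served = 20, newly_waiting = 10))
  expect_equal(service_throughput(10, 15, 20),
               c(served = 20, newly_waiting = 5))
})

test_that("capacity grows linearly by its yearly increment", {
  expect_equal(grow_capacity(1000, 125.85, 52), 1125.85)
  expect_equal(grow_capacity(300, 0, 52), 300)
  expect_equal(grow_capacity(2000, 259.57, 52), 2259.57)
  expect_equal(grow_capacity(1000, 125.85, 1 / 16), 1000 + 125.85 / 832)
})

test_that("the default model validates cleanly and conserves people", {
  m <- build_model(mhsd_params())
  expect_identical(validate_model(m), character())
  tr <- mhsd_simulate(config = cfg_mid())
  bands <- rowSums(tr$stocks[, c("distress_low", "distress_mod", "distress_high")])
  adults <- rowSums(tr$stocks[, c("pop_15_24", "pop_25_64", "pop_65p")])
  expect_lt(max(abs(bands - adults) / adults), 1e-6)
  # initial total population equals the configured regional total
  expect_equal(sum(tr$stocks[1, c("pop_0_14", "pop_15_24", "pop_25_64", "pop_65p")]),
               502524)
})

test_that("a missing parameter raises a named validation error", {
  p <- mhsd_params()
  p$att_high <- NULL
  expect_error(build_model(p), "att_high")
})

test_that("zero births, migration and mortality conserve the population", {
  p <- mhsd_params(births_weekly = 0, mig_0_14 = 0, mig_15_24 = 0,
                   mig_25_64 = 0, mig_65p = 0, mort_0_14 = 0, mort_15_24 = 0,
                   mort_25_64 = 0, mort_65p = 0, att_high = 0, att_mod = 0)
  # aging still moves people between groups; the total must be conserved
  tr <- mhsd_simulate(p, config = cfg_fast(2011, 2013))
  adults <- rowSums(tr$stocks[, c("pop_15_24", "pop_25_64", "pop_65p")])
  kids <- tr$stocks[, "pop_0_14"]
  expect_lt(max(abs(adults + kids - 502524)) / 502524, 1e-9)
})

test_that("zero onset, attempt and demand rates give zero outcome counters", {
  tr <- mhsd_simulate(params_all_off(), config = cfg_fast())
  expect_equal(unname(tr$counters), c(0, 0, 0))
  expect_true(all(tr$flows[, "recovery_services_high"] == 0))
})

test_that("attempts from a near-constant high stock follow the closed form", {
  # feedbacks disabled: no transitions, no services, no demography
  r <- 1e-4; f <- 0.08
  p <- mhsd_params(onset_low_mod = 0, onset_mod_high = 0, remit_mod_low = 0,
                   remit_high_mod = 0, att_high = r, att_mod = 0,
                   case_fatality = f, births_weekly = 0, mig_0_14 = 0,
                   mig_15_24 = 0, mig_25_64 = 0, mig_65p = 0, mort_0_14 = 0,
                   mort_15_24 = 0, mort_25_64 = 0, mort_65p = 0,
                   seek_mod_gp = 0, seek_high_gp = 0, seek_high_psy = 0,
                   seek_high_cmhc = 0, seek_high_out = 0, seek_mod_onl = 0,
                   ed_untreated_rate = 0, crisis_share = 0)
  H0 <- mhsd_initial_stocks(p)[["distress_high"]]
  tr <- mhsd_simulate(p, config = cfg_mid())
  Y <- 9
  # no-feedback idealisation: deaths = r * H * f * 52 * Y (H treated constant)
  expect_equal(unname(tr$counters["suicide_deaths"]), r * H0 * f * 52 * Y,
               tolerance = 0.01)
  expect_equal(unname(tr$counters["self_harm_hospitalizations"]),
               r * H0 * 52 * Y, tolerance = 0.01)
  # exact solution with the suicide outflow itself as the only depletion:
  # H(t) = H0 exp(-f r t), deaths over [t1, t2] = H0 (e^{-l t1} - e^{-l t2})
  l <- f * r
  deaths_exact <- H0 * (exp(-l * 52 * 10) - exp(-l * 52 * 19))
  expect_equal(unname(tr$counters["suicide_deaths"]), deaths_exact,
               tolerance = 1e-3)
})

test_that("zero capacity shuts service recovery and raises untreated prevalence", {
  p0 <- mhsd_params(cap_gp0 = 0, cap_psy0 = 0, cap_cmhc0 = 0, cap_onl0 = 0,
                    cap_out0 = 0, cap_inp0 = 0, cap_ed0 = 0, inc_gp = 0,
                    inc_psy = 0, inc_cmhc = 0)
  tr0 <- mhsd_simulate(p0, config = cfg_fast())
  expect_true(all(tr0$flows[, "recovery_services_high"] == 0))
  expect_true(all(tr0$flows[, "recovery_services_mod"] == 0))
  tr <- mhsd_simulate(config = cfg_fast())
  expect_true(all(tr0$report[, "prevalence_high"] >=
                    tr$report[, "prevalence_high"] - 1e-12))
})

test_that("raising an adverse determinant weight never reduces cumulative harm", {
  cfg <- cfg_fast()
  sh <- vapply(c(0.2, 0.4, 0.8), function(w) {
    tr <- mhsd_simulate(mhsd_params(w_unemp = w), scenario = "business_as_usual",
                        covid = "post", config = cfg)
    unname(tr$counters["self_harm_hospitalizations"])
  }, 0)
  expect_true(all(diff(sh) >= 0))
})

test_that("outcome summaries read counters and prevalence off the trajectory", {
  tr0 <- mhsd_simulate(params_all_off(), config = cfg_fast())
  s <- outcome_summary(tr0)
  expect_equal(s$self_harm_hospitalizations, 0)
  expect_equal(s$suicide_deaths, 0)
  expect_equal(s$ed_presentations, 0)
  expect_gt(s$prevalence_start, 0)
  short <- mhsd_simulate(config = cfg_fast(2011, 2025))
  expect_error(outcome_summary(short), "window")
  expect_silent(outcome_summary(short, end = 2025))
})

test_that("parameter YAML round-trips", {
  p <- mhsd_params(att_high = 4.2e-4)
  path <- tempfile(fileext = ".yaml")
  write_params_yaml(p, path)
  p2 <- read_params_yaml(path)
  expect_equal(unclass(p2)[names(p)], unclass(p)[names(p)])
})
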