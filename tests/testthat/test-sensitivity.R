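test_that("Latin hypercube samples are exactly stratified per parameter", {
  d4 <- lhs_design(c(m = 1), n = 4, half_width = 0.2, seed = 1)
  s4 <- lhs_sample(d4)
  bins <- floor((s4[, "m"] - 0.8) / 0.1 + 1e-12)
  expect_setequal(bins, 0:3)

  d <- lhs_design(c(a = 1, b = 0.5, c = 200), n = 100, half_width = 0.2, seed = 9)
  s <- lhs_sample(d)
  for (nm in colnames(s)) {
    lo <- d$nominal[[nm]] * 0.8
    w <- d$nominal[[nm]] * 0.4 / d$n
    bins <- floor((s[, nm] - lo) / w + 1e-9)
    expect_identical(sort(bins), as.numeric(0:99))
  }
  # marginal mean close to nominal (stratified-uniform variance bound)
  expect_lt(max(abs(colMeans(s) / d$nominal - 1)), 0.006)
})

test_that("zero half-width collapses every sample to the nominal value", {
  s <- lhs_sample(lhs_design(c(a = 2, b = 0.3), n = 10, half_width = 0, seed = 3))
  expect_true(all(s[, "a"] == 2))
  expect_true(all(s[, "b"] == 0.3))
})

test_that("designs are reproducible under a fixed seed", {
  d <- lhs_design(c(a = 1, b = 2), n = 20, half_width = 0.2, seed = 11)
  expect_identical(lhs_sample(d), lhs_sample(d))
  d2 <- lhs_design(c(a = 1, b = 2), n = 20, half_width = 0.2, seed = 12)
  expect_false(identical(lhs_sample(d), lhs_sample(d2)))
})

test_that("design validation rejects degenerate inputs", {
  expect_error(lhs_design(c(a = -1), n = 10), "positive")
  expect_error(lhs_design(c(a = 1), n = 1), "at least 2")
  expect_error(lhs_design(c(a = 1), n = 10, half_width = 1), "half_width")
})

test_that("scenario designs cover exactly the direct-effect parameters", {
  d4 <- scenario_lhs_design(builtin_scenarios()$tech_enabled_coordination)
  expect_setequal(names(d4$nominal),
                  c("u_max", "m_rec", "m_ref", "m_dis", "m_aod", "m_rel",
                    "m_emp", "m_home", "m_cap", "m_onl"))
  d2 <- scenario_lhs_design(builtin_scenarios()$capacity_growth_20)
  expect_setequal(names(d2$nominal), c("inc_gp", "inc_psy", "inc_cmhc"))
  expect_error(scenario_lhs_design(builtin_scenarios()$business_as_usual),
               "no direct-effect")
})

test_that("two-replicate intervals equal the type-7 percentiles of the draws", {
  spec <- builtin_scenarios()$capacity_growth_20
  res <- run_sensitivity(spec = spec,
                         design = scenario_lhs_design(spec, n = 2, seed = 5),
                         config = cfg_fast())
  for (i in seq_len(nrow(res$intervals))) {
    vals <- res$replicates[[res$intervals$metric[i]]]
    expect_equal(res$intervals$lower[i],
                 unname(quantile(vals, 0.025, type = 7)))
    expect_equal(res$intervals$upper[i],
                 unname(quantile(vals, 0.975, type = 7)))
  }
})

test_that("zero half-width collapses intervals to the central estimate", {
  spec <- builtin_scenarios()$standard_telehealth
  design <- lhs_design(c(m_rec = 1.09, m_dis = 0.76), n = 3, half_width = 0,
                       seed = 2)
  res <- run_sensitivity(spec = spec, design = design, config = cfg_fast())
  expect_equal(res$intervals$lower, res$intervals$central, tolerance = 1e-10)
  expect_equal(res$intervals$upper, res$intervals$central, tolerance = 1e-10)
})

test_that("the central estimate lies inside its interval and width shrinks with h", {
  spec <- builtin_scenarios()$tech_enabled_coordination
  res20 <- run_sensitivity(spec = spec,
                           design = scenario_lhs_design(spec, n = 10,
                                                        half_width = 0.2, seed = 4),
                           config = cfg_fast())
  res05 <- run_sensitivity(spec = spec,
                           design = scenario_lhs_design(spec, n = 10,
                                                        half_width = 0.05, seed = 4),
                           config = cfg_fast())
  expect_true(all(res20$intervals$lower <= res20$intervals$central + 1e-9))
  expect_true(all(res20$intervals$central <= res20$intervals$upper + 1e-9))
  w20 <- res20$intervals$upper - res20$intervals$lower
  w05 <- res05$intervals$upper - res05$intervals$lower
  expect_true(all(w05 < w20))
})

test_that("unknown sampled parameters are rejected", {
  spec <- builtin_scenarios()$tech_enabled_coordination
  design <- lhs_design(c(not_a_param = 1), n = 2, seed = 1)
  expect_error(
    suppressWarnings(run_sensitivity(spec = spec, design = design,
                                     config = cfg_fast(2011, 2022))),
    "failed")
})
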