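test_that("zero flows leave stocks constant and counters at zero", {
  m <- sf_model(stocks = c(A = 10, B = 5),
                flows = list(sf_flow("f", from = "A", to = "B",
                                     rate = function(x, p, t, aux) 0)),
                counters = list(sf_counter("c", "f", epoch = 2011)))
  tr <- integrate_model(m, config = sf_config(2011, 2014, dt = 1 / 4))
  expect_true(all(tr$stocks[, "A"] == 10))
  expect_true(all(tr$stocks[, "B"] == 5))
  expect_equal(unname(tr$counters["c"]), 0)
})

test_that("exponential decay matches its closed form", {
  cfg16 <- sf_config(2011, 2012, dt = 1 / 16)
  exact <- 100 * exp(-0.1 * 52)
  s_euler <- integrate_model(decay_model(), list(k = 0.1), cfg16)
  err16 <- abs(tail(s_euler$stocks[, "S"], 1) - exact) / exact
  # first-order scheme: documented relative error ~ k^2 T dt / 2 = 1.63%
  expect_lt(err16, 0.02)
  s_rk4 <- integrate_model(decay_model(), list(k = 0.1),
                           sf_config(2011, 2012, dt = 1 / 16, scheme = "rk4"))
  expect_lt(abs(tail(s_rk4$stocks[, "S"], 1) - exact) / exact, 1e-8)
  # halving dt halves the Euler error (first-order convergence)
  s32 <- integrate_model(decay_model(), list(k = 0.1),
                         sf_config(2011, 2012, dt = 1 / 32, record_every = 32))
  err32 <- abs(tail(s32$stocks[, "S"], 1) - exact) / exact
  expect_gt(err32 / err16, 0.4)
  expect_lt(err32 / err16, 0.6)
})

test_that("a 52-week model year at dt = 1/16 week is exactly 832 steps", {
  expect_identical(sf_config(2011, 2012, dt = 1 / 16)$n_steps, 832L)
  expect_identical(sf_config(2011, 2030, dt = 1 / 16)$n_steps, 19L * 832L)
})

test_that("validation returns one diagnostic per structural violation", {
  good <- closed_exchange_model()
  expect_identical(validate_model(good), character())

  bad_flow <- sf_model(stocks = c(A = 1),
                       flows = list(sf_flow("leak", from = "Z",
                                            rate = function(x, p, t, aux) 1)))
  d <- validate_model(bad_flow)
  expect_length(d, 1L)
  expect_match(d, "leak")
  expect_match(d, "Z")

  cyc <- sf_model(stocks = c(A = 1),
                  flows = list(sf_flow("f", from = "A",
                                       rate = function(x, p, t, aux) 0)),
                  aux = list(sf_aux("a", function(x, p, t, aux) aux$b, deps = "b"),
                             sf_aux("b", function(x, p, t, aux) aux$a, deps = "a")))
  d <- validate_model(cyc)
  expect_length(d, 1L)
  expect_match(d, "cycle")
  expect_match(d, "a, b")

  bad_counter <- sf_model(stocks = c(A = 1),
                          flows = list(sf_flow("f", from = "A",
                                               rate = function(x, p, t, aux) 0)),
                          counters = list(sf_counter("c", "nope")))
  expect_match(validate_model(bad_counter), "nope")

  expect_error(integrate_model(bad_flow), "validation")
})

test_that("mass in a closed subsystem is conserved to floating-point error", {
  tr <- integrate_model(closed_exchange_model(), config = sf_config(2011, 2030, dt = 1 / 16))
  total <- rowSums(tr$stocks)
  expect_lt(max(abs(total - 100)) / 100, 1e-6)
})

test_that("proportional rationing keeps every stock non-negative", {
  set.seed(7)
  for (rep in 1:20) {
    k1 <- runif(1, 0.5, 4); k2 <- runif(1, 0.5, 4); inflow <- runif(1, 0, 2)
    m <- sf_model(stocks = c(S = runif(1, 0, 5), R = 0),
                  flows = list(
                    sf_flow("in", to = "S", rate = function(x, p, t, aux) p$inflow),
                    sf_flow("o1", from = "S", to = "R",
                            rate = function(x, p, t, aux) p$k1 * x[["S"]]),
                    sf_flow("o2", from = "S",
                            rate = function(x, p, t, aux) p$k2 * max(x[["S"]] - 0.1, 0))))
    tr <- integrate_model(m, list(k1 = k1, k2 = k2, inflow = inflow),
                          sf_config(2011, 2012, dt = 1, record_every = 1))
    expect_true(all(tr$stocks >= 0))
    expect_true(all(is.finite(tr$stocks)))
  }
})

test_that("a non-finite flow aborts naming the flow and the time", {
  m <- sf_model(stocks = c(S = 100),
                flows = list(sf_flow("fragile", from = "S",
                                     rate = function(x, p, t, aux)
                                       if (x[["S"]] < 99) NaN else 5)))
  expect_error(integrate_model(m, config = sf_config(2011, 2012, dt = 1)),
               "fragile")
})

test_that("counters accumulate flow x dt only after their epoch", {
  m <- sf_model(stocks = c(S = 1),
                flows = list(sf_flow("events",
                                     rate = function(x, p, t, aux) 0.2)),
                counters = list(sf_counter("cum", "events", epoch = 2021)))
  tr <- integrate_model(m, config = sf_config(2011, 2030, dt = 1 / 16))
  # 0.2/week over 9 x 52 = 468 weeks
  expect_equal(unname(tr$counters["cum"]), 0.2 * 468, tolerance = 1e-10)
  i2020 <- which.min(abs(tr$times - 2020))
  expect_identical(unname(tr$counter_series[i2020, "cum"]), 0)
})

test_that("cumulative counters are non-decreasing after their epoch", {
  tr <- mhsd_simulate(config = cfg_fast())
  post <- tr$times >= 2021
  for (nm in colnames(tr$counter_series))
    expect_true(all(diff(tr$counter_series[post, nm]) >= 0))
})

test_that("trajectories export to tidy long CSV and back", {
  tr <- integrate_model(closed_exchange_model(),
                        config = sf_config(2011, 2012, dt = 1 / 4))
  df <- as.data.frame(tr, which = "stocks")
  expect_named(df, c("time", "variable", "value"))
  expect_setequal(unique(df$variable), c("A", "B"))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path, which = "stocks")
  back <- read.csv(path)
  expect_equal(back$value, df$value)
})
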