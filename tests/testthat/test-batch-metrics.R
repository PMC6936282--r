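two_point_ts <- function(c20, c2i, c10, c1i, dt = 10, cc0 = 50) {
  batch_time_series(c(0, dt), no3 = c(c20, c2i), no2 = c(c10, c1i),
                    cc0 = cc0)
}

test_that("efficiency and rate formulas match direct arithmetic", {
  ts <- two_point_ts(100, 10, 0, 45)
  expect_equal(nitrite_accumulation_efficiency(ts, 2), 50)
  expect_equal(nitrate_removal_efficiency(ts, 2), 90)
  expect_equal(specific_nitrate_rate(ts, 2), 0.18)
  expect_equal(specific_total_n_rate(ts, 2), 0.09)
})

test_that("degenerate states hit the documented edge values and errors", {
  # all removed nitrate present as nitrite
  ts_all <- two_point_ts(100, 10, 0, 90)
  expect_equal(nitrite_accumulation_efficiency(ts_all, 2), 100)
  expect_equal(specific_total_n_rate(ts_all, 2), 0)
  # unchanged nitrite: zero accumulation, total-N rate collapses to nitrate rate
  ts_flat <- two_point_ts(100, 10, 5, 5)
  expect_equal(nitrite_accumulation_efficiency(ts_flat, 2), 0)
  expect_equal(specific_total_n_rate(ts_flat, 2),
               specific_nitrate_rate(ts_flat, 2))
  # no nitrate consumed -> undefined ratio, not NaN
  ts_none <- two_point_ts(100, 100, 0, 5)
  expect_error(nitrite_accumulation_efficiency(ts_none, 2), "undefined")
  # nitrite rising more than nitrate fell -> warning, value > 100
  ts_over <- two_point_ts(100, 90, 0, 25)
  expect_warning(a <- nitrite_accumulation_efficiency(ts_over, 2), "100")
  expect_gt(a, 100)
})

test_that("d = c * (1 - a/100) holds on random batch states", {
  set.seed(11)
  for (i in 1:200) {
    c20 <- runif(1, 50, 500)
    c2i <- runif(1, 0, 0.95 * c20)
    c10 <- runif(1, 0, 10)
    c1i <- c10 + runif(1, 0, c20 - c2i)
    ts <- two_point_ts(c20, c2i, c10, c1i, dt = runif(1, 1, 24),
                       cc0 = runif(1, 10, 100))
    a <- suppressWarnings(nitrite_accumulation_efficiency(ts, 2))
    c_rate <- specific_nitrate_rate(ts, 2)
    d_rate <- specific_total_n_rate(ts, 2)
    expect_equal(d_rate, c_rate * (1 - a / 100), tolerance = 1e-12)
  }
})

test_that("removal efficiency is monotone while nitrate decreases", {
  ts <- gen_batch_series(conc_sd = 0)
  b <- metric_series(ts, "nitrate_removal")$value
  expect_true(all(diff(b) >= -1e-12))
  expect_true(all(b >= 0 & b <= 100))
})

test_that("specific growth rate matches its formula and unit invariance", {
  expect_equal(specific_growth_rate(100, 200, 2, 4), log(2) / 2)
  expect_equal(specific_growth_rate(50, 50, 0, 3), 0)
  expect_equal(specific_growth_rate(10, 10 * exp(1), 1, 2), 1)
  # invariant to rescaling the biomass unit
  expect_equal(specific_growth_rate(100, 180, 0, 5),
               specific_growth_rate(0.1, 0.18, 0, 5))
  expect_error(specific_growth_rate(0, 10, 0, 1), "positive")
  expect_error(specific_growth_rate(10, 20, 2, 2), "interval")
})

test_that("log-phase mu detects the generating slope", {
  # pure exponential: exact for any window
  ts <- batch_time_series(0:10, no3 = rep(100, 11), no2 = rep(0, 11),
                          biomass = 20 * exp(0.3 * (0:10)), cc0 = 20)
  expect_equal(log_phase_mu(ts, 3)$mu, 0.3, tolerance = 1e-12)
  expect_equal(log_phase_mu(ts, 5)$mu, 0.3, tolerance = 1e-12)
  # flat series
  ts_flat <- batch_time_series(0:5, rep(100, 6), rep(0, 6),
                               biomass = rep(30, 6), cc0 = 30)
  expect_equal(log_phase_mu(ts_flat)$mu, 0)
  # lag then exponential with known mu
  ts_lag <- gen_batch_series(lag_h = 9, mu = 0.25, times = 0:24)
  res <- log_phase_mu(ts_lag)
  expect_equal(res$mu, 0.25, tolerance = 0.01)
  expect_gte(res$t_start, 9)
  expect_error(log_phase_mu(ts_flat, window = 10), "at least")
})

test_that("time-series construction enforces its invariants", {
  expect_error(batch_time_series(c(0, 0, 1), rep(1, 3), rep(0, 3), cc0 = 1),
               "increasing")
  expect_error(batch_time_series(5, 1, 0, cc0 = 1), "2 time points")
  expect_error(batch_time_series(c(0, 1), c(-1, 0), c(0, 0), cc0 = 1),
               "non-negative")
})
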