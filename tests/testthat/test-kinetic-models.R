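test_that("single-substrate laws match hand-evaluated values at S = 100", {
  expect_equal(mu_single(100, params_from(table2$andrews_n)), 0.4632939,
               tolerance = 1e-6)
  expect_equal(mu_single(100, params_from(table2$aiba_n)), 0.4599337,
               tolerance = 1e-6)
  expect_equal(mu_single(100, params_from(table2$edwards_n)), 0.4733206,
               tolerance = 1e-6)
})

test_that("all laws vanish at S = 0 and as S -> Inf", {
  for (row in table2[1:3]) {
    p <- params_from(row)
    expect_identical(mu_single(0, p), 0)
    expect_lt(mu_single(1e8, p), 1e-3 * p$mu_max)
  }
})

test_that("rates stay within (0, mu_max) for valid parameters", {
  S <- c(1e-3, 1, 50, 500, 5000, 1e5)
  for (row in table2) {
    p <- params_from(row)
    mu <- mu_single(S, p)
    expect_true(all(mu > 0))
    expect_true(all(mu < p$mu_max))
  }
})

test_that("parameter validation rejects non-physical constants", {
  expect_error(single_params(-0.5, 10, 100, "andrews"), "mu_max")
  expect_error(single_params(0.5, 0, 100, "aiba"), "ks")
  expect_error(single_params(0.5, 10, -1, "aiba"), "ki")
  expect_error(single_params(0.5, 100, 50, "edwards"), "ki > ks")
  expect_error(single_params(0.5, 10, 100, "monod"))
  expect_error(mu_single(-5, params_from(table2$andrews_n)), "non-negative")
})

test_that("double-substrate model is the product of normalized factors", {
  dp <- double_params(table2_double15$mu_max, "andrews",
                      table2_double15$ks_n, table2_double15$ki_n,
                      "andrews", table2_double15$ks_c, table2_double15$ki_c)
  expect_equal(mu_double(100, 500, dp), 0.4627734, tolerance = 1e-6)
  expect_identical(mu_double(0, 500, dp), 0)
  expect_identical(mu_double(100, 0, dp), 0)
  expect_lt(mu_double(100, 1e9, dp), 1e-3 * dp$mu_max)
})

test_that("double model factorizes into single laws sharing mu_max", {
  set.seed(7)
  kinds <- model_kinds()
  for (i in 1:20) {
    k1 <- sample(kinds, 1); k2 <- sample(kinds, 1)
    mm <- runif(1, 0.2, 0.8)
    ks1 <- runif(1, 5, 100); ki1 <- runif(1, 500, 5000)
    ks2 <- runif(1, 5, 100); ki2 <- runif(1, 500, 5000)
    dp <- double_params(mm, k1, ks1, ki1, k2, ks2, ki2)
    p1 <- single_params(mm, ks1, ki1, k1)
    p2 <- single_params(mm, ks2, ki2, k2)
    S1 <- runif(1, 10, 3000); S2 <- runif(1, 10, 3000)
    expect_equal(mu_double(S1, S2, dp) * mm,
                 mu_single(S1, p1) * mu_single(S2, p2), tolerance = 1e-12)
  }
})

test_that("Arrhenius evaluation matches direct computation and is monotone", {
  ap <- arrhenius_params(77.48, 13.80)
  expect_equal(mu_max_at_temperature(298.15, ap), 0.2960736,
               tolerance = 1e-6)
  expect_equal(mu_max_at_temperature(1e12, ap), 77.48, tolerance = 1e-6)
  expect_equal(mu_max_at_temperature(300, arrhenius_params(5, 0)), 5)
  T_K <- seq(280, 320, by = 2)
  expect_true(all(diff(mu_max_at_temperature(T_K, ap)) > 0))
  expect_error(mu_max_at_temperature(-3, ap), "positive")
})

test_that("ln(mu_max) is affine in 1/T (three collinear points)", {
  ap <- arrhenius_params(50, 20)
  inv_T <- c(0.0031, 0.0032, 0.0033)
  lmu <- log(mu_max_at_temperature(1 / inv_T, ap))
  expect_equal(lmu[2], mean(lmu[c(1, 3)]), tolerance = 1e-12)
})

test_that("optimal substrate: Andrews closed form and numeric search agree", {
  p <- params_from(table2$andrews_n)
  expect_equal(optimal_substrate(p), sqrt(17.14 * 1782.07), tolerance = 1e-9)
  expect_equal(optimal_substrate(single_params(0.5, 30, 30, "andrews")), 30)
  # closed form against a dense grid oracle, 0.1% agreement
  S_grid <- exp(seq(log(1e-2), log(1e6), length.out = 20000))
  expect_equal(optimal_substrate(p), S_grid[which.max(mu_single(S_grid, p))],
               tolerance = 1e-3)
  # aiba/edwards numeric optimum beats the whole grid
  for (row in list(table2$aiba_n, table2$edwards_n)) {
    pp <- params_from(row)
    s_star <- optimal_substrate(pp)
    expect_gte(mu_single(s_star, pp), max(mu_single(S_grid, pp)) - 1e-10)
  }
})

test_that("rate unit conversions are mutual inverses", {
  expect_equal(per_day_to_per_hour(per_hour_to_per_day(0.23)), 0.23)
  expect_equal(per_day_to_per_hour(24), 1)
})
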