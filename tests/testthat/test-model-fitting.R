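test_that("r_squared follows its definition", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(1, 1), c(1, 2)), "zero variance")
  expect_error(r_squared(1:3, 1:4), "equal length")
})

test_that("noiseless single-substrate data is recovered for every law", {
  for (nm in names(table2)) {
    row <- table2[[nm]]
    grid <- if (grepl("_c$", nm)) carbon_grid else nitrate_grid
    tab <- gen_growth_table(params_from(row), s1 = grid)
    fit <- fit_single(tab, "s1", row$kind)
    expect_true(fit$converged)
    expect_lt(rel_err(fit$params$mu_max, row$mu_max), 0.005)
    expect_lt(rel_err(fit$params$ks, row$ks), 0.005)
    expect_lt(rel_err(fit$params$ki, row$ki), 0.005)
    expect_gte(fit$r_squared, 0.9999)
  }
})

test_that("under-determined or malformed tables are rejected", {
  small <- growth_table(c(50, 100, 150), c(0.3, 0.4, 0.45))
  expect_error(fit_single(small, "s1", "andrews"), "at least 4")
  expect_error(fit_single(growth_table(nitrate_grid, rep(0.4, 12)),
                          "s2", "aiba"), "s2")
  expect_error(fit_double(growth_table(nitrate_grid, rep(0.4, 12)),
                          "aiba", "aiba"), "s2")
  expect_error(growth_table(c(-50, 100), c(0.1, 0.2)), "positive")
})

test_that("collinear paired design recovers mu_max with a warning", {
  dp <- double_params(table2_double15$mu_max,
                      "andrews", table2_double15$ks_n, table2_double15$ki_n,
                      "andrews", table2_double15$ks_c, table2_double15$ki_c)
  tab <- gen_growth_table(dp)  # S2 = 5 * S1
  expect_warning(fit <- fit_double(tab, "andrews", "andrews"), "collinear")
  expect_true(fit$converged)
  expect_true(fit$collinear)
  expect_lt(rel_err(fit$params$mu_max, table2_double15$mu_max), 0.005)
  expect_gte(fit$r_squared, 0.9999)
})

test_that("a crossed concentration grid identifies all five constants", {
  dp <- double_params(table2_double15$mu_max,
                      "andrews", table2_double15$ks_n, table2_double15$ki_n,
                      "andrews", table2_double15$ks_c, table2_double15$ki_c)
  g <- expand.grid(s1 = c(50, 150, 300, 500, 1000, 2000),
                   s2 = c(250, 750, 1500, 2500, 5000, 10000))
  tab <- gen_growth_table(dp, s1 = g$s1, s2 = g$s2)
  fit <- fit_double(tab, "andrews", "andrews")
  expect_false(fit$collinear)
  expect_lt(rel_err(fit$params$mu_max, table2_double15$mu_max), 0.01)
  expect_lt(rel_err(fit$params$s1$ks, table2_double15$ks_n), 0.01)
  expect_lt(rel_err(fit$params$s1$ki, table2_double15$ki_n), 0.01)
  expect_lt(rel_err(fit$params$s2$ks, table2_double15$ks_c), 0.01)
  expect_lt(rel_err(fit$params$s2$ki, table2_double15$ki_c), 0.01)
})

test_that("fit_all emits the full 15-model comparison layout", {
  dp <- double_params(table2_double15$mu_max,
                      "andrews", table2_double15$ks_n, table2_double15$ki_n,
                      "andrews", table2_double15$ks_c, table2_double15$ki_c)
  tab <- gen_growth_table(dp)
  fits <- suppressWarnings(fit_all(tab))
  rep <- fit_report(fits)
  expect_equal(nrow(rep), 15L)
  expect_equal(rep$fitting_number, 1:15)
  expect_equal(rep$model_no3[1:3], c("aiba", "edwards", "andrews"))
  expect_true(all(is.na(rep$model_toc[1:3])))
  expect_equal(rep$model_toc[4:6], c("aiba", "edwards", "andrews"))
  expect_equal(rep$model_no3[7:15], rep(c("aiba", "edwards", "andrews"), 3))
  expect_equal(rep$model_toc[7:15], rep(c("aiba", "edwards", "andrews"),
                                        each = 3))
  # self-consistency: the generating combination ranks best among doubles
  doubles <- rep[7:15, ]
  best_double <- doubles$fitting_number[which.max(doubles$r_squared)]
  expect_equal(best_double, 15L)
  # single-substrate nitrate fits all converge on smooth data
  expect_true(all(rep$converged[1:3]))
  expect_true(all(rep$r_squared[1:3] > 0.98))
  ranked <- rank_fits(fits)
  expect_true(all(diff(ranked$r_squared) <= 0))
  expect_error(fit_all(growth_table(numeric(), numeric())), "empty")
})

test_that("noisy mu data still recovers mu_max to a few percent", {
  p <- params_from(table2$andrews_n)
  errs <- vapply(1:100, function(s) {
    tab <- gen_growth_table(p, mu_sd = 0.01, seed = s)
    fit <- fit_single(tab, "s1", "andrews")
    if (!fit$converged) return(NA_real_)
    rel_err(fit$params$mu_max, p$mu_max)
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.05)
})

test_that("fitted SSE matches a brute-force grid oracle", {
  set.seed(42)
  for (kind in model_kinds()) {
    for (i in 1:5) {
      truth <- single_params(runif(1, 0.2, 0.8),
                             exp(runif(1, log(5), log(200))),
                             exp(runif(1, log(800), log(20000))), kind)
      tab <- gen_growth_table(truth)
      fit <- fit_single(tab, "s1", kind)
      expect_true(fit$converged)
      oracle <- grid_oracle_sse(tab$s1_mg_l, tab$mu_per_h, kind)
      expect_lte(fit$sse, oracle * (1 + 1e-6) + 1e-12)
    }
  }
})

test_that("Arrhenius regression recovers generating parameters exactly", {
  truth <- arrhenius_params(arrhenius_truth$A, arrhenius_truth$E)
  ser <- gen_arrhenius_series(truth)
  fit <- fit_arrhenius(ser$temperature_K, ser$mu_max)
  expect_equal(fit$params$A, arrhenius_truth$A, tolerance = 1e-9)
  expect_equal(fit$params$E, arrhenius_truth$E, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # two exact points interpolate with R^2 = 1
  fit2 <- fit_arrhenius(c(293.15, 313.15),
                        mu_max_at_temperature(c(293.15, 313.15), truth))
  expect_equal(fit2$params$E, arrhenius_truth$E, tolerance = 1e-9)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_arrhenius(c(293, 303), c(0, 0.3)), "positive")
  expect_error(fit_arrhenius(293.15, 0.3), ">= 2")
})
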