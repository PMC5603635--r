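test_that("bland_altman computes bias and n-1 scatter", {
  ba <- bland_altman(c(1, -1, 0))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, 1)
  expect_equal(bland_altman(c(5, 5, 5, 5)), list(bias = 5, sd = 0, n = 4))
  expect_error(bland_altman(c(2)), class = "ventrobust_invalid_parameter")
  expect_error(bland_altman(c(1, NA, Inf)),
               class = "ventrobust_invalid_parameter")
})

test_that("bland_altman matches the moments of a uniform sample", {
  x <- withr::with_seed(1, runif(1e5, -1, 1))
  ba <- bland_altman(x)
  # uniform[-1,1]: mean 0 (SE = 1/sqrt(3n)), sd 1/sqrt(3)
  expect_lt(abs(ba$bias), 3 / sqrt(3 * 1e5))
  expect_equal(ba$sd, 1 / sqrt(3), tolerance = 0.01)
})

test_that("variance comparison puts the larger variance on top", {
  a <- withr::with_seed(2, rnorm(500))
  b <- withr::with_seed(3, rnorm(500, sd = 3))
  vc <- compare_variances(a, b)
  expect_gte(vc$f_statistic, 1)
  expect_true(vc$significant_at_alpha)
  # symmetric in its arguments
  vc2 <- compare_variances(b, a)
  expect_equal(vc2$f_statistic, vc$f_statistic)
  expect_equal(vc2$p_value, vc$p_value)
  # agrees with the standard two-sample F test
  ref <- stats::var.test(b, a)
  expect_equal(vc$f_statistic, unname(ref$statistic))
  expect_equal(vc$p_value, ref$p.value)
})

test_that("identical samples give F = 1 and no significance", {
  x <- withr::with_seed(4, rnorm(50))
  vc <- compare_variances(x, x)
  expect_equal(vc$f_statistic, 1)
  expect_false(vc$significant_at_alpha)
})

test_that("degenerate variance inputs are rejected", {
  expect_error(compare_variances(c(1), c(1, 2, 3)),
               class = "ventrobust_invalid_parameter")
  expect_error(compare_variances(rep(2, 10), rep(7, 10)),
               class = "ventrobust_undefined_ratio")
})

test_that("non-normal errors are flagged but still tested", {
  skewed <- withr::with_seed(5, rexp(200))
  normal <- withr::with_seed(6, rnorm(200))
  expect_warning(compare_variances(skewed, normal), "normality")
})

test_that("a degenerate single-level sweep reduces to the baseline", {
  pool <- study_pool(20, seed = 19)
  pats <- pool_patterns(pool)
  m <- train_ensemble_select_best(pats, pool_references(pool),
                                  training_plan(n_restarts = 1, seed = 4,
                                                max_epochs = 200))
  sw <- run_sweep(pool, m, kinds = c("RN", "TD"), levels = 0, master_seed = 3)
  refs <- pool_references(pool)
  base_mlf <- bland_altman(vapply(pool, function(r)
    mlf_estimate_crs(r$regular), numeric(1)) - refs)
  expect_equal(sw$tables$MLF_RN$bias, base_mlf$bias)
  expect_equal(sw$tables$MLF_RN$sd, base_mlf$sd)
  # at level 0 the RN and TD tables coincide for both estimators
  expect_equal(sw$tables$MLF_RN, sw$tables$MLF_TD)
  expect_equal(sw$tables$ANN_RN, sw$tables$ANN_TD)
  expect_true(all(sw$tables$MLF_RN$n == length(pool)))
})

test_that("sweeps are bit-reproducible under one master seed", {
  pool <- study_pool(15, seed = 23)
  pats <- pool_patterns(pool)
  m <- train_ensemble_select_best(pats, pool_references(pool),
                                  training_plan(n_restarts = 1, seed = 4,
                                                max_epochs = 150))
  s1 <- run_sweep(pool, m, kinds = "RN", levels = c(0, 10, 50), master_seed = 99)
  s2 <- run_sweep(pool, m, kinds = "RN", levels = c(0, 10, 50), master_seed = 99)
  expect_identical(s1$errors, s2$errors)
  expect_identical(s1$tables, s2$tables)
  # extending the grid never reshuffles existing draws
  s3 <- run_sweep(pool, m, kinds = "RN", levels = c(0, 10, 30, 50),
                  master_seed = 99)
  expect_equal(s3$errors[s3$errors$level %in% c(0, 10, 50), ],
               s1$errors, ignore_attr = TRUE)
})

test_that("sweep tables and comparisons have the documented shape", {
  pool <- study_pool(15, seed = 27)
  pats <- pool_patterns(pool)
  m <- train_ensemble_select_best(pats, pool_references(pool),
                                  training_plan(n_restarts = 1, seed = 4,
                                                max_epochs = 150))
  sw <- run_sweep(pool, m, levels = c(0, 2, 50), master_seed = 5)
  expect_named(sw$tables, c("MLF_RN", "MLF_TD", "ANN_RN", "ANN_TD"))
  for (tab in sw$tables) {
    expect_equal(tab$level, c(0, 2, 50))
    expect_true(all(tab$n == 15))
  }
  expect_equal(nrow(sw$comparisons), 6)
  expect_true(all(sw$comparisons$f_statistic >= 1))
  dir <- withr::local_tempdir()
  paths <- write_sweep_tables(sw, dir)
  expect_true(all(file.exists(file.path(
    dir, c("error_table_rn.tsv", "error_table_td.tsv",
           "variance_comparison.tsv")))))
  rn <- read.delim(file.path(dir, "error_table_rn.tsv"))
  expect_named(rn, c("level", "mlf_bias", "mlf_sd", "ann_bias", "ann_sd"))
  expect_equal(rn$mlf_sd, sw$tables$MLF_RN$sd, tolerance = 1e-9)
})

test_that("MLF-only sweeps run without a model", {
  pool <- study_pool(10, seed = 29)
  sw <- run_sweep(pool, NULL, kinds = "TD", levels = c(0, 50))
  expect_named(sw$tables, c("MLF_TD"))
  expect_null(sw$comparisons)
})
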