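test_that("complete tables pass through imputation unchanged", {
  d <- simulate_cohort(cohort_spec(missing_rate_waist = 0,
                                   missing_rate_bodyfat = 0), seed = 1)
  imp <- fcs_impute(d, m = 5, seed = 1)
  expect_s3_class(imp, "imputation_set")
  expect_equal(imp$m, 5L)
  for (tb in imp$tables) expect_identical(tb, d)
})

test_that("MCAR deletion is repaired in expectation", {
  withr::with_seed(77, {
    n <- 800
    x <- rnorm(n)
    y <- 2 + 0.8 * x + rnorm(n, 0, 0.5)
    truth_mean <- mean(y)
    ymis <- y
    ymis[sample(n, round(0.13 * n))] <- NA
    d <- data.frame(x = x, y = ymis)
  })
  imp <- fcs_impute(d, m = 10, n_iter = 10, seed = 3)
  pooled_mean <- mean(vapply(imp$tables, function(tb) mean(tb$y),
                             numeric(1)))
  # Monte-Carlo error of a 13%-missing mean at n = 800
  expect_lt(abs(pooled_mean - truth_mean), 4 * sd(y) / sqrt(0.13 * n))
  for (tb in imp$tables) expect_false(anyNA(tb))
})

test_that("chains converge (PSR below 1.05) on well-specified data", {
  d <- simulate_cohort(seed = 21)
  imp <- fcs_impute(d, impute_vars = c("waist", "body_fat"),
                    predictor_vars = c("bmi", "age", "sex", "group01",
                                       "parent_education", "movement"),
                    m = 10, n_iter = 20, seed = 4)
  expect_length(imp$psr, 2)
  expect_true(all(imp$psr < 1.05))
  expect_equal(imp$m, 10L)
})

test_that("imputation rejects degenerate inputs", {
  d <- data.frame(x = 1:5, y = rep(NA_real_, 5))
  expect_error(fcs_impute(d, m = 2), "entirely missing")
  d2 <- data.frame(x = rnorm(20), y = c(letters[1:19], NA))
  expect_error(fcs_impute(d2, m = 2), "not numeric")
  d3 <- data.frame(x = rnorm(20), y = c(rnorm(19), NA))
  expect_error(fcs_impute(d3, impute_vars = "x", m = 2),
               "outside impute_vars")
})

test_that("Rubin pooling reproduces hand-computed combining rules", {
  p <- pool_rubin(c(1, 3), c(1, 1), df_complete = Inf)
  expect_equal(p$qbar, 2)
  expect_equal(p$wbar, 1)
  expect_equal(p$b, 2)
  expect_equal(p$t_total, 4)  # 1 + (1 + 1/2) * 2
  expect_equal(p$t_stat, 1)
})

test_that("identical estimates collapse the between variance", {
  p <- pool_rubin(rep(1.5, 6), rep(0.2, 6), df_complete = 100)
  expect_equal(p$b, 0)
  expect_equal(p$t_total, p$wbar)
  expect_equal(p$df, 100)
})

test_that("pooling is order-invariant and total variance dominates W", {
  withr::with_seed(11, {
    for (i in 1:25) {
      m <- sample(3:30, 1)
      est <- rnorm(m)
      va <- runif(m, 0.1, 2)
      p <- pool_rubin(est, va, df_complete = 50)
      perm <- sample(m)
      p2 <- pool_rubin(est[perm], va[perm], df_complete = 50)
      expect_equal(p, p2)
      expect_gte(p$t_total, p$wbar)
      expect_lte(p$ci_low, p$qbar)
      expect_gte(p$ci_high, p$qbar)
    }
  })
})

test_that("with many imputations the pooled estimate converges", {
  withr::with_seed(13, {
    theta <- 0.7
    est <- rnorm(2000, theta, 0.05)
    p <- pool_rubin(est, rep(0.01, 2000), df_complete = Inf)
    expect_lt(abs(p$qbar - theta), 0.005)
    # T = W + (1 + 1/m) B -> v_within + v_between
    expect_equal(p$t_total, 0.01 + 0.05^2, tolerance = 0.1)
  })
})

test_that("pooling rejects fewer than two imputations", {
  expect_error(pool_rubin(1, 1), "at least 2")
  expect_error(pool_rubin(c(1, 2), c(1, -1)), "variances")
})
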