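test_that("standardization z-scores continuous columns and is idempotent", {
  d <- simulate_cohort(cohort_spec(missing_rate_waist = 0,
                                   missing_rate_bodyfat = 0), seed = 5)
  z <- standardize_cohort(d)
  expect_lt(abs(mean(z$bmi)), 1e-12)
  expect_lt(abs(sd(z$bmi) - 1), 1e-12)
  expect_identical(z$sex, d$sex)          # binary untouched
  expect_identical(z$obesity, d$obesity)
  z2 <- standardize_cohort(z)
  expect_lt(max(abs(z2$bmi - z$bmi)), 1e-12)
  d$flat <- 1.5
  expect_error(standardize_cohort(d, cols = "flat"), "zero variance")
})

test_that("standardized simple-regression slope equals Pearson r", {
  withr::with_seed(8, {
    x <- rnorm(120)
    y <- 0.4 * x + rnorm(120)
  })
  d <- standardize_cohort(data.frame(x = x, y = y))
  slope <- unname(coef(lm(y ~ x, data = d))["x"])
  expect_lt(abs(slope - cor(x, y)), 1e-10)
})

test_that("OLS recovers a noise-free linear construction exactly", {
  withr::with_seed(15, {
    n <- 80
    d <- data.frame(bmi = rnorm(n), group01 = rbinom(n, 1, 0.5),
                    age = rnorm(n), sex = rbinom(n, 1, 0.5),
                    parent_education = sample(0:3, n, TRUE),
                    movement = rnorm(n))
  })
  d$y <- 0.3 * d$bmi + 0.2 * d$group01 - 0.1 * d$age + 0.05 * d$sex +
    0.02 * d$parent_education + 0.07 * d$movement
  fit <- suppressWarnings(fit_roi_model(d, "y", "bmi", interaction = FALSE))
  est <- setNames(fit$terms$estimate, fit$terms$term)
  expect_lt(abs(est[["bmi"]] - 0.3), 1e-10)
  expect_lt(abs(est[["group01"]] - 0.2), 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
})

test_that("the moderation fit keeps its type-I error near nominal", {
  pvals <- vapply(1:300, function(s) {
    withr::with_seed(1000 + s, {
      n <- 100
      d <- data.frame(y = rnorm(n), bmi = rnorm(n),
                      group01 = rbinom(n, 1, 0.5), age = rnorm(n),
                      sex = rbinom(n, 1, 0.5),
                      parent_education = sample(0:3, n, TRUE),
                      movement = rnorm(n))
    })
    fit <- fit_roi_model(d, "y", "bmi", interaction = TRUE)
    i <- fit$terms$term == "bmi"
    2 * pt(-abs(fit$terms$estimate[i] / sqrt(fit$terms$variance[i])),
           fit$df_resid)
  }, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("collinear terms are reported by name", {
  d <- data.frame(y = rnorm(30), bmi = rnorm(30), group01 = 1,
                  age = rnorm(30), sex = 0, parent_education = 1,
                  movement = rnorm(30))
  d$dup <- d$bmi
  expect_error(fit_roi_model(d, "y", "bmi", covariates = c("age", "dup")),
               "collinear")
})

test_that("semipartial r matches its closed forms", {
  expect_equal(semipartial_r(0, 0.5, 100), 0)
  expect_equal(round(semipartial_r(2.99, 0.06, 152), 3), 0.235)
  # simple regression: r_sp is the Pearson correlation
  withr::with_seed(23, {
    x <- rnorm(60)
    y <- 0.5 * x + rnorm(60)
  })
  fit <- lm(y ~ x)
  tval <- summary(fit)$coefficients["x", "t value"]
  r2 <- summary(fit)$r.squared
  expect_lt(abs(semipartial_r(tval, r2, fit$df.residual) - cor(x, y)),
            1e-10)
  expect_error(semipartial_r(1, 0.5, 0), "positive")
  expect_error(semipartial_r(1, 1.2, 10), "r2_full")
})

test_that("BH adjustment matches hand and brute-force oracles", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.3), 0.3)
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  withr::with_seed(99, {
    for (i in 1:1000) {
      p <- runif(sample(1:25, 1))^sample(1:3, 1)
      expect_equal(fdr_bh(p), bh_bruteforce(p))
    }
  })
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("group contrasts reproduce printed summary-table statistics", {
  # BMI: 16.68 (2.39, n=81) ADHD vs 16.48 (2.27, n=78) TD
  g <- group_compare_summary(16.68, 2.39, 81, 16.48, 2.27, 78)
  expect_equal(round(g$d, 2), -0.09)
  expect_equal(round(g$t, 2), -0.54)
  expect_equal(round(g$d_ci_low, 2), -0.40)
  expect_equal(round(g$d_ci_high, 2), 0.23)
  # percent body fat and waist circumference rows
  bf <- group_compare_summary(23.04, 8.11, 81, 22.31, 6.77, 78)
  expect_equal(round(bf$d, 2), -0.10)
  expect_equal(round(bf$t, 2), -0.61)
  ws <- group_compare_summary(57.93, 7.94, 81, 57.34, 5.69, 78)
  expect_equal(round(ws$d, 2), -0.09)
  expect_equal(round(ws$t, 2), -0.54)
  # obesity status: 16/81 vs 11/78 with continuity correction
  ob <- group_compare_binary(16, 81, 11, 78)
  expect_equal(round(ob$phi, 2), 0.06)
  expect_equal(round(ob$p, 2), 0.46)
  # without correction the uncorrected chi-square would give phi ~ 0.08
  chi_raw <- suppressWarnings(
    chisq.test(matrix(c(16, 65, 11, 67), 2, byrow = TRUE),
               correct = FALSE)$statistic)
  expect_equal(round(sqrt(unname(chi_raw) / 159), 2), 0.08)
})

test_that("identical groups give null contrasts", {
  d <- data.frame(group = rep(c("ADHD", "TD"), each = 20),
                  v = rep(rnorm(20), 2), b = rep(c(0, 1), 20))
  g <- group_compare(d, "v")
  expect_equal(g$t, 0)
  expect_equal(g$d, 0)
  gb <- group_compare(d, "b")
  expect_equal(gb$phi, 0)
})

test_that("group_compare on raw data agrees with its summary path", {
  d <- simulate_cohort(seed = 12)
  g <- group_compare(d, "bmi")
  a <- d$bmi[d$group == "ADHD"]
  t <- d$bmi[d$group == "TD"]
  ref <- group_compare_summary(mean(a), sd(a), length(a),
                               mean(t), sd(t), length(t))
  expect_equal(g$d, ref$d)
  expect_equal(g$t, ref$t)
})

test_that("BMI arithmetic and LMS classification work", {
  expect_equal(round(bmi(20, 1.10), 2), 16.53)
  expect_error(bmi(-1, 1), "positive")
  lms <- data.frame(age = rep(4:7, 2), sex = rep(c(1, 2), each = 4),
                    L = -1.5, M = 16.0, S = 0.08)
  # BMI at the median row -> z = 0 -> 50th percentile
  expect_equal(lms_zscore(16.0, 5, 1, lms), 0)
  expect_false(bmi_status(16.0, 5, 1, lms))
  expect_true(bmi_status(19.5, 5, 1, lms))
  # closed-form z inverts the forward LMS transform
  z <- lms_zscore(18.2, 6, 2, lms)
  forward <- 16.0 * (1 + (-1.5) * 0.08 * z)^(1 / -1.5)
  expect_lt(abs(forward - 18.2), 1e-10)
  expect_error(lms_zscore(16, 12, 1, lms), "outside")
  # empirical-reference path
  ref <- seq(12, 22, by = 0.1)
  expect_true(bmi_status(21.9, reference = ref))
  expect_false(bmi_status(15, reference = ref))
})

test_that("the ROI pipeline drops a null interaction and is deterministic", {
  d <- simulate_cohort(cohort_spec(missing_rate_waist = 0,
                                   missing_rate_bodyfat = 0), seed = 31)
  res <- run_roi_pipeline(d, metrics = "rni", predictors = "bmi")
  expect_equal(nrow(res), 10)
  expect_true(all(res$model == 2L))
  expect_true(all(res$term == "bmi"))
  expect_true(all(res$fdr_p >= res$p))
  expect_true(all(res$ci_low <= res$beta & res$beta <= res$ci_high))
  res2 <- run_roi_pipeline(d, metrics = "rni", predictors = "bmi")
  expect_identical(res, res2)
})

test_that("a strong induced moderation is retained as model 1", {
  d <- simulate_cohort(cohort_spec(missing_rate_waist = 0,
                                   missing_rate_bodyfat = 0), seed = 32)
  # inject a large interaction into one ROI column
  d$rni_nacc <- d$rni_nacc + 1.5 * scale(d$bmi)[, 1] * d$group01
  res <- run_roi_pipeline(d, metrics = "rni", predictors = "bmi")
  expect_true(all(res$model == 1L))
  expect_true(any(res$interaction_fdr_p < 0.05))
  expect_true(grepl(":", res$term[1]))
})
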