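test_that("cohort generation is deterministic per seed", {
  expect_identical(simulate_cohort(seed = 3), simulate_cohort(seed = 3))
  expect_false(identical(simulate_cohort(seed = 3),
                         simulate_cohort(seed = 4)))
})

test_that("group sizes, labels and covariate ranges match the configuration", {
  d <- simulate_cohort(seed = 1)
  expect_equal(nrow(d), 159)
  expect_equal(sum(d$group == "ADHD"), 81)
  expect_equal(sum(d$group == "TD"), 78)
  expect_true(all(d$age >= 4 & d$age <= 7))
  expect_true(all(d$sex %in% 0:1))
  expect_true(all(d$parent_education %in% 0:3))
  expect_true(all(d$movement > 0 & d$movement <= 1.7))
  expect_equal(ncol(d) - 11L, 40L)  # 4 metrics x 10 ROIs
})

test_that("group anthropometric means sit near their targets", {
  spec <- cohort_spec()
  d <- simulate_cohort(spec, seed = 10)
  se_adhd <- spec$bmi_sd[1] / sqrt(spec$n_adhd)
  se_td <- spec$bmi_sd[2] / sqrt(spec$n_td)
  expect_lt(abs(mean(d$bmi[d$group == "ADHD"]) - 16.68), 3 * se_adhd)
  expect_lt(abs(mean(d$bmi[d$group == "TD"]) - 16.48), 3 * se_td)
})

test_that("missingness follows the configured MAR rates", {
  d0 <- simulate_cohort(cohort_spec(missing_rate_waist = 0,
                                    missing_rate_bodyfat = 0), seed = 2)
  expect_false(anyNA(d0))
  # empirical rate over several cohorts converges to the target
  rates <- vapply(1:10, function(s) {
    mean(is.na(simulate_cohort(seed = s)$waist))
  }, numeric(1))
  # binomial tolerance: 3 SEs at n = 1590 pooled
  expect_lt(abs(mean(rates) - 0.138), 3 * sqrt(0.138 * 0.862 / 1590))
  # MAR structure: missingness more likely in the ADHD group
  d <- do.call(rbind, lapply(1:10, function(s) simulate_cohort(seed = s)))
  p_adhd <- mean(is.na(d$waist[d$group == "ADHD"]))
  p_td <- mean(is.na(d$waist[d$group == "TD"]))
  expect_gt(p_adhd, p_td)
})

test_that("the configured brain-BMI slope is recovered on average", {
  betas <- vapply(1:40, function(s) {
    d <- standardize_cohort(simulate_cohort(cohort_spec(
      missing_rate_waist = 0, missing_rate_bodyfat = 0), seed = s))
    fit <- fit_roi_model(d, "rni_nacc", "bmi", interaction = FALSE)
    fit$terms$estimate[fit$terms$term == "bmi"]
  }, numeric(1))
  # Monte-Carlo error ~ 0.08 / sqrt(40)
  expect_lt(abs(mean(betas) - 0.22), 4 * 0.08 / sqrt(40))
  # null columns stay null
  beta0 <- vapply(1:40, function(s) {
    d <- standardize_cohort(simulate_cohort(cohort_spec(
      missing_rate_waist = 0, missing_rate_bodyfat = 0), seed = s))
    fit <- fit_roi_model(d, "hnt_caudate", "bmi", interaction = FALSE)
    fit$terms$estimate[fit$terms$term == "bmi"]
  }, numeric(1))
  expect_lt(abs(mean(beta0)), 4 * 0.08 / sqrt(40))
})

test_that("obesity status flags the top of the BMI distribution", {
  d <- simulate_cohort(seed = 6)
  expect_true(all(d$bmi[d$obesity == 1] >
                    max(d$bmi[d$obesity == 0]) - 1e-12))
  expect_equal(mean(d$obesity), 0.15, tolerance = 0.02)
})
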