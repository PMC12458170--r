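#' Default ROI set of the ROI analysis
#'
#' Eight subcortical regions analyzed as hemisphere averages plus left and
#' right anterior insula kept separate.
#' @return character vector of 10 ROI identifiers.
#' @export
default_rois <- function() {
  c("nacc", "putamen", "caudate", "pallidum", "ventral_dc", "thalamus",
    "amygdala", "hippocampus", "insula_lh", "insula_rh")
}

#' @rdname default_rois
#' @export
default_metrics <- function() c("rni", "rnd", "rnt", "hnt")

#' Synthetic-cohort specification
#'
#' Parameters of the synthetic pediatric cohort generator. Defaults encode
#' the study conditions: 81 ADHD and 78 typically developing children;
#' group anthropometric means/SDs of BMI 16.68 (2.39) vs 16.48 (2.27),
#' percent body fat 23.04 (8.11) vs 22.31 (6.77) and waist circumference
#' 57.93 (7.94) vs 57.34 (5.69) cm; a standardized brain-BMI slope of 0.22
#' on the affected metric columns; missing-at-random deletion of 13.8% of
#' waist and 12.6% of body-fat values; overweight/obesity flagged above the
#' 85th BMI percentile of the synthetic distribution.
#'
#' @param n_adhd,n_td group sizes.
#' @param bmi_mean,bmi_sd,bodyfat_mean,bodyfat_sd,waist_mean,waist_sd
#'   length-2 vectors `c(adhd, td)`.
#' @param anthro_cor latent correlation tying body fat and waist to BMI.
#' @param brain_effect_beta standardized slope of the affected ROI metric
#'   columns on BMI.
#' @param effect_cols metric columns (`"<metric>_<roi>"`) carrying the
#'   slope; all other metric columns are null.
#' @param covariate_effects named standardized effects of the covariates on
#'   every metric column.
#' @param missing_rate_waist,missing_rate_bodyfat MAR deletion rates.
#' @param obesity_cutoff_percentile BMI percentile (0-1) above which
#'   `obesity = 1`.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_adhd = 81L, n_td = 78L,
                        bmi_mean = c(16.68, 16.48),
                        bmi_sd = c(2.39, 2.27),
                        bodyfat_mean = c(23.04, 22.31),
                        bodyfat_sd = c(8.11, 6.77),
                        waist_mean = c(57.93, 57.34),
                        waist_sd = c(7.94, 5.69),
                        anthro_cor = 0.6,
                        brain_effect_beta = 0.22,
                        effect_cols = c("rni_nacc", "rni_insula_rh"),
                        covariate_effects = c(age = 0.10, sex = 0.05,
                                              parent_education = 0.05,
                                              movement = -0.10),
                        missing_rate_waist = 0.138,
                        missing_rate_bodyfat = 0.126,
                        obesity_cutoff_percentile = 0.85) {
  stopifnot(n_adhd > 0, n_td > 0,
            missing_rate_waist >= 0, missing_rate_waist < 1,
            missing_rate_bodyfat >= 0, missing_rate_bodyfat < 1,
            obesity_cutoff_percentile > 0, obesity_cutoff_percentile < 1)
  structure(as.list(environment()), class = "cohort_spec")
}

# intercept of a logistic MAR model calibrated so that mean(p) == rate
calibrate_mar_intercept <- function(eta, rate) {
  if (rate == 0) return(-Inf)
  stats::uniroot(function(a) mean(stats::plogis(a + eta)) - rate,
                 c(-30, 30), tol = 1e-10)$root
}

#' Simulate a cohort table
#'
#' Draws a per-subject table with group label, covariates (age uniform on
#' 4-7 years, sex ~ Bernoulli(0.65), 4-level parent education, positively
#' skewed scanner movement below the QC cutoff), group-specific
#' anthropometrics (body fat and waist share a latent correlation with
#' BMI), 40 ROI metric z-score columns (`<metric>_<roi>`) generated as
#' `beta * z(BMI) + covariate effects + noise` with unit total variance,
#' an overweight/obesity indicator from the within-sample BMI percentile,
#' and missing-at-random deletion of waist and body fat with probability
#' logistic in group and age, calibrated to the specified rates.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; the table is fully reproducible per seed.
#' @return data.frame with one row per child.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(as.integer(seed), {
    n <- spec$n_adhd + spec$n_td
    grp <- rep(c(1L, 0L), c(spec$n_adhd, spec$n_td))  # 1 = ADHD
    gidx <- ifelse(grp == 1L, 1L, 2L)                 # index into c(adhd, td)

    age <- stats::runif(n, 4, 7)
    sex <- stats::rbinom(n, 1, 0.65)
    parent_education <- sample(0:3, n, replace = TRUE,
                               prob = c(0.03, 0.20, 0.35, 0.42))
    # mean RMS movement (mm): lognormal, truncated below the 1.7 mm QC
    # cutoff since the analyzed cohort is post-exclusion
    movement <- stats::rlnorm(n, log(0.8), 0.55)
    while (any(movement > 1.7)) {
      i <- movement > 1.7
      movement[i] <- stats::rlnorm(sum(i), log(0.8), 0.55)
    }

    zb <- stats::rnorm(n)
    bmi <- spec$bmi_mean[gidx] + spec$bmi_sd[gidx] * zb
    rho <- spec$anthro_cor
    mix <- function(m, s) {
      m[gidx] + s[gidx] * (rho * zb + sqrt(1 - rho^2) * stats::rnorm(n))
    }
    body_fat <- mix(spec$bodyfat_mean, spec$bodyfat_sd)
    waist <- mix(spec$waist_mean, spec$waist_sd)
    obesity <- as.integer(bmi > stats::quantile(bmi, spec$obesity_cutoff_percentile))

    df <- data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      group = ifelse(grp == 1L, "ADHD", "TD"),
      group01 = grp, age = age, sex = sex,
      parent_education = parent_education, movement = movement,
      bmi = bmi, body_fat = body_fat, waist = waist, obesity = obesity,
      stringsAsFactors = FALSE
    )

    ce <- spec$covariate_effects
    systematic_base <-
      ce[["age"]] * as.numeric(scale(age)) +
      ce[["sex"]] * sex +
      ce[["parent_education"]] * as.numeric(scale(parent_education)) +
      ce[["movement"]] * as.numeric(scale(movement))
    for (metric in default_metrics()) {
      for (roi in default_rois()) {
        col <- paste(metric, roi, sep = "_")
        beta <- if (col %in% spec$effect_cols) spec$brain_effect_beta else 0
        sys <- beta * as.numeric(scale(bmi)) + systematic_base
        resid_var <- max(1 - stats::var(sys), 0.05)
        df[[col]] <- sys + stats::rnorm(n, 0, sqrt(resid_var))
      }
    }

    eta <- 0.5 * grp + 0.5 * as.numeric(scale(age))
    for (v in c("waist", "body_fat")) {
      rate <- if (v == "waist") spec$missing_rate_waist else spec$missing_rate_bodyfat
      if (rate > 0) {
        p <- stats::plogis(calibrate_mar_intercept(eta, rate) + eta)
        df[[v]][stats::runif(n) < p] <- NA_real_
      }
    }
    df
  })
}
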