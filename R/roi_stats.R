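#' Standardize analysis columns of a cohort table
#'
#' z-scores the outcome and continuous predictor columns; binary 0/1
#' columns (sex, group, obesity) are left untouched so that standardized
#' regression coefficients keep the usual interpretation. Scaling
#' parameters are recorded in the `"standardization"` attribute, and
#' applying the function twice is a no-op on already-scaled columns.
#'
#' @param data data.frame.
#' @param cols columns to z-score; default: every numeric non-binary
#'   column.
#' @return data.frame with scaled columns and a `"standardization"`
#'   attribute (data.frame of column, center, scale).
#' @export
standardize_cohort <- function(data, cols = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(cols)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    binary <- vapply(num, function(v) {
      all(stats::na.omit(data[[v]]) %in% c(0, 1))
    }, logical(1))
    cols <- num[!binary]
  }
  params <- data.frame(column = cols, center = NA_real_, scale = NA_real_)
  for (i in seq_along(cols)) {
    v <- cols[i]
    x <- data[[v]]
    mu <- mean(x, na.rm = TRUE)
    sd <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(sd) || sd == 0) {
      stop("column '", v, "' has zero variance; cannot standardize")
    }
    data[[v]] <- (x - mu) / sd
    params$center[i] <- mu
    params$scale[i] <- sd
  }
  attr(data, "standardization") <- params
  data
}

#' Fit one ROI regression model by ordinary least squares
#'
#' Fits `outcome ~ predictor * group + covariates` (moderation model) or,
#' with `interaction = FALSE`, `outcome ~ predictor + group + covariates`
#' (reduced model) on a single completed dataset, and returns per-term
#' estimates with sampling variances, the residual degrees of freedom and
#' the model R-squared — the quantities Rubin's rules pool across
#' imputations.
#'
#' @param data completed (no missing cells in the model variables)
#'   data.frame.
#' @param outcome,predictor,group column names; `group` must be 0/1.
#' @param covariates character vector of covariate columns.
#' @param interaction include the predictor-by-group interaction?
#' @return list with `terms` (data.frame: term, estimate, variance),
#'   `df_resid`, `r2`, and `fit` (the `lm` object).
#' @export
fit_roi_model <- function(data, outcome, predictor, group = "group01",
                          covariates = c("age", "sex", "parent_education",
                                         "movement"),
                          interaction = TRUE) {
  vars <- c(outcome, predictor, group, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(data[vars])) stop("model variables contain missing values")
  rhs <- if (interaction) paste0(predictor, " * ", group) else
    paste0(predictor, " + ", group)
  fml <- stats::as.formula(paste(outcome, "~", rhs, "+",
                                 paste(covariates, collapse = " + ")))
  fit <- stats::lm(fml, data = data)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient model; collinear terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  list(terms = data.frame(term = rownames(co),
                          estimate = co[, 1],
                          variance = co[, 2]^2,
                          row.names = NULL),
       df_resid = fit$df.residual,
       r2 = sm$r.squared,
       fit = fit)
}

#' Semipartial correlation from a t statistic
#'
#' `r_sp = sign(t) |t| sqrt(1 - R2) / sqrt(df_resid)`: the correlation
#' between the outcome and the unique part of one predictor, recovered
#' from that predictor's t statistic and the full-model R-squared. In a
#' single-predictor model it equals the Pearson correlation.
#'
#' @param t_stat t statistic of the term.
#' @param r2_full R-squared of the full model (in `[0, 1)`).
#' @param df_resid residual degrees of freedom (> 0).
#' @return scalar semipartial correlation.
#' @export
semipartial_r <- function(t_stat, r2_full, df_resid) {
  if (df_resid <= 0) stop("df_resid must be positive")
  if (r2_full < 0 || r2_full >= 1) stop("r2_full must be in [0, 1)")
  sign(t_stat) * abs(t_stat) * sqrt(1 - r2_full) / sqrt(df_resid)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; a thin wrapper over
#' [stats::p.adjust()] with input validation.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
fdr_bh <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# pooled per-term row for one (metric, roi, predictor, model, term)
pool_model_term <- function(fits, term, df_complete) {
  est <- vapply(fits, function(f) {
    f$terms$estimate[f$terms$term == term]
  }, numeric(1))
  va <- vapply(fits, function(f) {
    f$terms$variance[f$terms$term == term]
  }, numeric(1))
  pooled <- pool_rubin(est, va, df_complete)
  r2 <- mean(vapply(fits, `[[`, numeric(1), "r2"))
  pooled$r_sp <- semipartial_r(pooled$t_stat, r2, df_complete)
  pooled
}

#' ROI moderation-then-reduction regression pipeline
#'
#' For every metric x ROI x anthropometric predictor the moderation model
#' `metric_roi ~ predictor * group + age + sex + parent education +
#' movement` is fitted on each imputed dataset (columns z-scored per
#' dataset), pooled by Rubin's rules, and the interaction p-values are
#' FDR-corrected across ROIs within each metric x predictor family. If no
#' interaction survives at `alpha`, the model is refitted without the
#' interaction and the pooled main effect of the predictor is reported
#' with within-family FDR correction.
#'
#' @param imputations an `imputation_set` from [fcs_impute()], a list of
#'   completed data.frames, or one complete data.frame.
#' @param metrics,rois,predictors families to analyze; metric x ROI
#'   outcome columns must be named `<metric>_<roi>`.
#' @param covariates covariate columns.
#' @param group 0/1 group column (moderator).
#' @param alpha significance level of the FDR interaction gate.
#' @return data.frame with one row per metric x ROI x predictor: `metric`,
#'   `roi`, `predictor`, `model` (1 = moderation retained, 2 = reduced),
#'   `term`, `beta`, `se`, `t_stat`, `df`, `p`, `ci_low`, `ci_high`,
#'   `r_sp`, `fdr_p`, plus the pooled interaction p (`interaction_p`,
#'   `interaction_fdr_p`) that drove the gate.
#' @export
run_roi_pipeline <- function(imputations,
                             metrics = default_metrics(),
                             rois = default_rois(),
                             predictors = c("bmi", "body_fat", "waist",
                                            "obesity"),
                             covariates = c("age", "sex", "parent_education",
                                            "movement"),
                             group = "group01",
                             alpha = 0.05) {
  tables <- if (inherits(imputations, "imputation_set")) {
    imputations$tables
  } else if (is.data.frame(imputations)) {
    list(imputations)
  } else {
    imputations
  }
  if (length(tables) == 1L) tables <- rep(tables, 2L)  # degenerate pooling
  tables <- lapply(tables, standardize_cohort)

  n <- nrow(tables[[1]])
  out <- list()
  for (metric in metrics) {
    for (pred in predictors) {
      cols <- paste(metric, rois, sep = "_")
      inter_term <- paste0(pred, ":", group)
      df1 <- n - (length(covariates) + 4L)  # int., pred, group, interaction
      df2 <- n - (length(covariates) + 3L)
      fits1 <- lapply(cols, function(cl) {
        lapply(tables, fit_roi_model, outcome = cl, predictor = pred,
               group = group, covariates = covariates, interaction = TRUE)
      })
      inter <- lapply(fits1, pool_model_term, term = inter_term,
                      df_complete = df1)
      inter_p <- vapply(inter, `[[`, numeric(1), "p")
      inter_fdr <- fdr_bh(inter_p)
      moderated <- any(inter_fdr < alpha)

      for (i in seq_along(rois)) {
        if (moderated) {
          pooled <- inter[[i]]
          row <- data.frame(metric = metric, roi = rois[i], predictor = pred,
                            model = 1L, term = inter_term)
          fdr_p <- inter_fdr[i]
        } else {
          fits2 <- lapply(tables, fit_roi_model, outcome = cols[i],
                          predictor = pred, group = group,
                          covariates = covariates, interaction = FALSE)
          pooled <- pool_model_term(fits2, pred, df2)
          row <- data.frame(metric = metric, roi = rois[i], predictor = pred,
                            model = 2L, term = pred)
          fdr_p <- NA_real_  # filled after the family loop
        }
        out[[length(out) + 1L]] <- cbind(
          row,
          data.frame(beta = pooled$qbar, se = sqrt(pooled$t_total),
                     t_stat = pooled$t_stat, df = pooled$df, p = pooled$p,
                     ci_low = pooled$ci_low, ci_high = pooled$ci_high,
                     r_sp = pooled$r_sp, fdr_p = fdr_p,
                     interaction_p = inter_p[i],
                     interaction_fdr_p = inter_fdr[i]))
      }
    }
  }
  res <- do.call(rbind, out)
  # within-family (metric x predictor, across ROIs) FDR on the reported term
  for (metric in metrics) {
    for (pred in predictors) {
      sel <- res$metric == metric & res$predictor == pred
      if (all(res$model[sel] == 2L)) {
        res$fdr_p[sel] <- fdr_bh(res$p[sel])
      }
    }
  }
  rownames(res) <- NULL
  res
}

#' Body mass index and CDC-style weight status
#'
#' `bmi()` is weight in kilograms divided by the square of height in
#' meters. `bmi_status()` classifies a child as overweight/obese when the
#' age- and sex-specific BMI percentile reaches the cutoff: with an LMS
#' reference table (columns `age`, `sex`, `L`, `M`, `S`) the percentile
#' comes from the Box-Cox z-score `((BMI/M)^L - 1) / (L S)` (log form at
#' L = 0); with an empirical reference distribution the percentile is its
#' empirical CDF.
#'
#' @param weight_kg,height_m positive anthropometrics.
#' @return `bmi()`: numeric BMI (kg/m^2).
#' @export
bmi <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0) || any(height_m <= 0)) {
    stop("weight and height must be positive")
  }
  weight_kg / height_m^2
}

#' @rdname bmi
#' @param bmi_value numeric BMI.
#' @param age,sex child age (years) and sex code matching the LMS table.
#' @param lms_table optional data.frame with columns `age`, `sex`, `L`,
#'   `M`, `S`; the row with matching sex and nearest age is used, erroring
#'   if `age` is outside the table's range for that sex.
#' @param reference optional numeric vector: an empirical BMI distribution
#'   used instead of an LMS table.
#' @param cutoff_percentile percentile (0-1) at or above which status is
#'   `TRUE` (default 0.85, the overweight/obese threshold).
#' @return `bmi_status()`: logical; `lms_zscore()`: numeric z.
#' @export
bmi_status <- function(bmi_value, age = NULL, sex = NULL, lms_table = NULL,
                       reference = NULL, cutoff_percentile = 0.85) {
  if (any(bmi_value <= 0)) stop("BMI must be positive")
  if (!is.null(lms_table)) {
    z <- lms_zscore(bmi_value, age, sex, lms_table)
    return(stats::pnorm(z) >= cutoff_percentile)
  }
  if (!is.null(reference)) {
    pct <- stats::ecdf(reference)(bmi_value)
    return(pct >= cutoff_percentile)
  }
  stop("either an LMS table or an empirical reference must be supplied")
}

#' @rdname bmi
#' @export
lms_zscore <- function(bmi_value, age, sex, lms_table) {
  needed <- c("age", "sex", "L", "M", "S")
  if (!all(needed %in% names(lms_table))) {
    stop("LMS table must have columns: ", paste(needed, collapse = ", "))
  }
  vapply(seq_along(bmi_value), function(i) {
    rows <- lms_table[lms_table$sex == sex[i], ]
    if (!nrow(rows)) stop("no LMS rows for sex '", sex[i], "'")
    if (age[i] < min(rows$age) || age[i] > max(rows$age)) {
      stop("age ", age[i], " outside the LMS table range [",
           min(rows$age), ", ", max(rows$age), "]")
    }
    r <- rows[which.min(abs(rows$age - age[i])), ]
    if (abs(r$L) < 1e-12) {
      log(bmi_value[i] / r$M) / r$S
    } else {
      ((bmi_value[i] / r$M)^r$L - 1) / (r$L * r$S)
    }
  }, numeric(1))
}

#' Two-group contrasts with effect sizes
#'
#' `group_compare()` contrasts a measure between two groups of a cohort
#' table; `group_compare_summary()` does the same from printed summary
#' statistics (group 1 first, group 2 second): pooled-SD two-sample t
#' test, Cohen's d = (mean2 - mean1) / pooled SD, and a 95% CI for d from
#' the normal approximation `Var(d) = (n1+n2)/(n1 n2) + d^2/(2(n1+n2))`.
#' `group_compare_binary()` contrasts two proportions with the Yates
#' continuity-corrected chi-squared test and `phi = sqrt(chi2 / N)`.
#'
#' @param data cohort data.frame.
#' @param measure column to contrast (continuous, or 0/1 for the binary
#'   path).
#' @param group grouping column with exactly two levels; `ref` names the
#'   level treated as group 1 (the study convention puts ADHD first so
#'   that d > 0 means the second, TD, group scores higher).
#' @param ref level of `group` used as group 1.
#' @return list with `t`, `p`, `d`, `d_ci_low`, `d_ci_high`, group
#'   means/SDs/ns (continuous), or `chi2`, `p`, `phi`, proportions
#'   (binary).
#' @export
group_compare <- function(data, measure, group = "group", ref = "ADHD") {
  g <- data[[group]]
  lev <- unique(g)
  if (length(lev) != 2) stop("grouping column must have exactly two levels")
  if (!ref %in% lev) stop("ref level '", ref, "' not present")
  other <- setdiff(lev, ref)
  x1 <- stats::na.omit(data[[measure]][g == ref])
  x2 <- stats::na.omit(data[[measure]][g == other])
  if (length(x1) < 2 || length(x2) < 2) {
    stop("each group needs at least 2 observations")
  }
  if (all(c(x1, x2) %in% c(0, 1))) {
    return(group_compare_binary(sum(x1), length(x1), sum(x2), length(x2)))
  }
  group_compare_summary(mean(x1), stats::sd(x1), length(x1),
                        mean(x2), stats::sd(x2), length(x2))
}

#' @rdname group_compare
#' @param mean1,sd1,n1,mean2,sd2,n2 per-group summary statistics.
#' @export
group_compare_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  d <- (mean2 - mean1) / sp
  se_diff <- sp * sqrt(1 / n1 + 1 / n2)
  t <- (mean2 - mean1) / se_diff
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(t), df)
  vd <- (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
  z <- stats::qnorm(0.975)
  list(t = t, p = p, df = df, d = d,
       d_ci_low = d - z * sqrt(vd), d_ci_high = d + z * sqrt(vd),
       mean1 = mean1, sd1 = sd1, n1 = n1, mean2 = mean2, sd2 = sd2, n2 = n2)
}

#' @rdname group_compare
#' @param x1,x2 event counts in the two groups.
#' @export
group_compare_binary <- function(x1, n1, x2, n2) {
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  chi2 <- unname(ct$statistic)
  list(chi2 = chi2, p = unname(ct$p.value),
       phi = sqrt(chi2 / (n1 + n2)),
       prop1 = x1 / n1, prop2 = x2 / n2, n1 = n1, n2 = n2)
}
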