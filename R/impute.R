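#' Fully conditional specification multiple imputation
#'
#' Chained-equations imputation for continuous variables: each incomplete
#' column is regressed on the predictor set (using current values of the
#' other imputed columns), regression coefficients and residual variance
#' are drawn from their Bayesian posterior (normal / scaled inverse
#' chi-squared under a flat prior), and missing entries are filled with
#' posterior-predictive draws. Several chains are run in parallel streams;
#' after `n_iter` burn-in sweeps a completed dataset is saved every
#' `n_iter` sweeps until `m` datasets are collected across chains.
#' Convergence is monitored with the potential scale reduction (PSR,
#' Gelman-Rubin) statistic of each imputed variable's per-sweep mean of
#' imputed cells, computed over the latter half of the chains.
#'
#' @param data data.frame; missingness only in numeric columns.
#' @param impute_vars columns to impute; default: all columns containing
#'   `NA`. An error is raised if any such column is non-numeric or is
#'   entirely missing.
#' @param predictor_vars complete numeric columns used as regressors
#'   (default: every complete numeric column). Incomplete columns other
#'   than the one being imputed always enter with their current values.
#' @param m number of imputed datasets (default 20).
#' @param n_iter sweeps between saved imputations (and burn-in length).
#' @param n_chains number of parallel chains (>= 2 for PSR).
#' @param seed integer seed.
#' @return Object of class `imputation_set`: list with `tables` (m
#'   completed data.frames), `m`, `psr` (named per-variable PSR), `seed`.
#' @export
fcs_impute <- function(data, impute_vars = NULL, predictor_vars = NULL,
                       m = 20L, n_iter = 50L, n_chains = 2L, seed = 1L) {
  stopifnot(is.data.frame(data), m >= 2, n_iter >= 1, n_chains >= 2)
  has_na <- vapply(data, anyNA, logical(1))
  if (is.null(impute_vars)) impute_vars <- names(data)[has_na]
  extra_na <- setdiff(names(data)[has_na], impute_vars)
  if (length(extra_na)) {
    stop("missing values outside impute_vars: ", paste(extra_na, collapse = ", "))
  }
  for (v in impute_vars) {
    if (!is.numeric(data[[v]])) {
      stop("incomplete column '", v, "' is not numeric; ",
           "no imputation model is defined for it")
    }
    if (all(is.na(data[[v]]))) stop("column '", v, "' is entirely missing")
  }
  if (!length(impute_vars)) {
    return(structure(list(tables = rep(list(data), m), m = as.integer(m),
                          psr = numeric(0), seed = as.integer(seed)),
                     class = "imputation_set"))
  }
  if (is.null(predictor_vars)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    predictor_vars <- setdiff(num[!has_na[num]], impute_vars)
  }
  if (!length(predictor_vars)) stop("no complete numeric predictor columns")

  miss <- lapply(data[impute_vars], is.na)
  quota <- diff(round(seq(0, m, length.out = n_chains + 1)))

  run <- withr::with_seed(as.integer(seed), {
    tables <- vector("list", 0)
    trace <- array(NA_real_, c(n_chains, 2L * n_iter * max(quota),
                               length(impute_vars)),
                   dimnames = list(NULL, NULL, impute_vars))
    n_sweeps_done <- integer(n_chains)
    for (ch in seq_len(n_chains)) {
      # working matrix: predictors then imputed variables; only the
      # imputed columns change across sweeps
      M <- cbind(1, as.matrix(data[c(predictor_vars, impute_vars)]))
      vcol <- 1L + length(predictor_vars) + seq_along(impute_vars)
      # initialize missing cells by resampling observed values
      for (vi in seq_along(impute_vars)) {
        mis <- miss[[vi]]
        M[mis, vcol[vi]] <- sample(M[!mis, vcol[vi]], sum(mis),
                                   replace = TRUE)
      }
      saved <- 0L
      sweep <- 0L
      while (saved < quota[ch]) {
        sweep <- sweep + 1L
        for (vi in seq_along(impute_vars)) {
          j <- vcol[vi]
          M[, j] <- draw_imputation(M[, j], miss[[vi]],
                                    M[, -j, drop = FALSE])
          trace[ch, sweep, vi] <- mean(M[miss[[vi]], j])
        }
        if (sweep > n_iter && (sweep - n_iter) %% n_iter == 0) {
          saved <- saved + 1L
          cur <- data
          for (vi in seq_along(impute_vars)) {
            cur[[impute_vars[vi]]] <- M[, vcol[vi]]
          }
          tables[[length(tables) + 1L]] <- cur
        }
        if (sweep >= 2L * n_iter * max(quota)) break
      }
      n_sweeps_done[ch] <- sweep
    }
    list(tables = tables, trace = trace, n_sweeps = min(n_sweeps_done))
  })

  psr <- vapply(seq_along(impute_vars), function(vi) {
    ns <- run$n_sweeps
    keep <- seq(floor(ns / 2) + 1L, ns)   # latter half of each chain
    gelman_rubin(run$trace[, keep, vi, drop = FALSE][, , 1])
  }, numeric(1))
  names(psr) <- impute_vars

  structure(list(tables = run$tables, m = length(run$tables), psr = psr,
                 seed = as.integer(seed)),
            class = "imputation_set")
}

# one Bayesian linear-regression imputation step for variable y
# (flat prior: sigma^2 ~ RSS / chisq(df), beta | sigma ~ N(betahat, sigma^2 (X'X)^-1))
draw_imputation <- function(y, mis, X) {
  Xo <- X[!mis, , drop = FALSE]
  yo <- y[!mis]
  qr_x <- qr(Xo)
  if (qr_x$rank < ncol(Xo)) stop("rank-deficient imputation model")
  betahat <- qr.coef(qr_x, yo)
  rss <- sum(qr.resid(qr_x, yo)^2)
  df <- length(yo) - ncol(Xo)
  if (df <= 0) stop("too few observed rows for the imputation model")
  sigma2 <- rss / stats::rchisq(1, df)
  R <- qr.R(qr_x)
  beta <- betahat + sqrt(sigma2) *
    backsolve(R, stats::rnorm(ncol(Xo)))
  y[mis] <- drop(X[mis, , drop = FALSE] %*% beta) +
    stats::rnorm(sum(mis), 0, sqrt(sigma2))
  y
}

# Gelman-Rubin potential scale reduction over a chains x iterations matrix
gelman_rubin <- function(tr) {
  tr <- tr[, colSums(is.na(tr)) == 0, drop = FALSE]
  n <- ncol(tr)
  if (n < 2) return(NA_real_)
  W <- mean(apply(tr, 1, stats::var))
  B <- n * stats::var(rowMeans(tr))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rubin's-rules pooling of multiply imputed estimates
#'
#' Combines m per-imputation estimates and sampling variances:
#' `Qbar = mean(estimates)`, `Wbar = mean(variances)`, `B` the sample
#' variance of the estimates, total variance `T = Wbar + (1 + 1/m) B`.
#' Degrees of freedom follow the Barnard-Rubin small-sample formula when a
#' finite complete-data df is given (classic Rubin df otherwise); the test
#' statistic, two-sided p and 95% confidence interval use Student's t.
#'
#' @param estimates numeric vector of m per-imputation estimates (m >= 2).
#' @param variances numeric vector of m per-imputation sampling variances.
#' @param df_complete residual degrees of freedom of the complete-data
#'   analysis (`Inf` for the asymptotic Rubin df).
#' @param conf_level confidence level (default 0.95).
#' @return list with `qbar`, `wbar`, `b`, `t_total`, `df`, `t_stat`, `p`,
#'   `ci_low`, `ci_high`, `m`.
#' @export
pool_rubin <- function(estimates, variances, df_complete = Inf,
                       conf_level = 0.95) {
  m <- length(estimates)
  if (m < 2) stop("pooling requires at least 2 imputations")
  if (length(variances) != m) stop("estimates and variances differ in length")
  if (any(!is.finite(estimates)) || any(variances <= 0)) {
    stop("estimates must be finite and variances > 0")
  }
  qbar <- mean(estimates)
  wbar <- mean(variances)
  b <- stats::var(estimates)
  t_total <- wbar + (1 + 1 / m) * b
  if (b > 0) {
    lambda <- (1 + 1 / m) * b / t_total
    df_old <- (m - 1) / lambda^2
    if (is.finite(df_complete)) {
      df_obs <- (df_complete + 1) / (df_complete + 3) * df_complete * (1 - lambda)
      df <- 1 / (1 / df_old + 1 / df_obs)
    } else {
      df <- df_old
    }
  } else {
    df <- df_complete
  }
  t_stat <- qbar / sqrt(t_total)
  p <- if (is.finite(df)) 2 * stats::pt(-abs(t_stat), df) else
    2 * stats::pnorm(-abs(t_stat))
  q <- if (is.finite(df)) stats::qt(1 - (1 - conf_level) / 2, df) else
    stats::qnorm(1 - (1 - conf_level) / 2)
  list(qbar = qbar, wbar = wbar, b = b, t_total = t_total, df = df,
       t_stat = t_stat, p = p,
       ci_low = qbar - q * sqrt(t_total),
       ci_high = qbar + q * sqrt(t_total), m = m)
}
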