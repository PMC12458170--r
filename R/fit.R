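#' Linear forward operator of the RSI model
#'
#' Assembles the design matrix mapping compartment spherical-harmonic
#' coefficients to the measured multi-shell signal. Columns are the
#' restricted block (SH basis at the scheme directions, each order-l block
#' scaled by that compartment's [compartment_response()] at the row's
#' b-value), the hindered block (same construction), and one free-water
#' column (`Y00 * exp(-b D_free)`). On b = 0 rows every anisotropic (l > 0)
#' column is zero and the isotropic columns carry the constant `Y00`
#' structure.
#'
#' @param scheme an [acquisition_scheme()].
#' @param model an [compartment_model()].
#' @return n_volumes x n_coef matrix (31 columns for lmax 4/4/0), with a
#'   `"blocks"` attribute giving the column index of each compartment block.
#' @export
rsi_design <- function(scheme, model = compartment_model()) {
  stopifnot(inherits(scheme, "rsi_scheme"), inherits(model, "rsi_model"))
  ub <- sort(unique(scheme$bvals))
  row_of_b <- match(scheme$bvals, ub)

  block <- function(compartment, lmax) {
    basis <- sh_basis(scheme$bvecs, lmax)
    idx <- sh_index(lmax)
    resp <- sapply(ub, function(b) {
      sapply(seq(0, lmax, by = 2), function(l) {
        compartment_response(b, model, compartment, l)
      })
    })                                       # n_orders x n_shells
    lpos <- match(idx$l, seq(0, lmax, by = 2))
    scale <- t(resp)[row_of_b, lpos, drop = FALSE]  # n_rows x n_coef
    basis * scale
  }

  restricted <- block("restricted", model$lmax_restricted)
  hindered <- block("hindered", model$lmax_hindered)
  y00 <- 1 / sqrt(4 * pi)
  free <- matrix(y00 * exp(-scheme$bvals * model$free_diffusivity), ncol = 1)

  X <- cbind(restricted, hindered, free)
  nr <- ncol(restricted)
  nh <- ncol(hindered)
  colnames(X) <- c(paste0("restricted_", colnames(restricted)),
                   paste0("hindered_", colnames(hindered)),
                   "free_l0m+0")
  attr(X, "blocks") <- list(restricted = seq_len(nr),
                            hindered = nr + seq_len(nh),
                            free = nr + nh + 1L)
  X
}

# ridge solver operator: 31 x n_volumes matrix applying Tikhonov-regularized
# least squares with lambda relative to the largest singular value;
# ridge_lambda = 0 gives the exact pseudoinverse.
rsi_solver <- function(design, ridge_lambda = 1e-6) {
  if (ridge_lambda < 0) stop("ridge_lambda must be >= 0")
  sv <- svd(design)
  keep <- sv$d > max(sv$d) * 1e-12
  lam <- ridge_lambda * max(sv$d)
  f <- sv$d[keep] / (sv$d[keep]^2 + lam^2)
  sv$v[, keep, drop = FALSE] %*% (f * t(sv$u[, keep, drop = FALSE]))
}

#' Fit the RSI model in one voxel
#'
#' Solves the regularized linear least-squares deconvolution
#' `min ||design %*% x - signal||^2 + (lambda s_max)^2 ||x||^2` and
#' partitions the solution into restricted / hindered / free coefficient
#' blocks. Voxels with non-finite signal or non-positive mean b0 are
#' flagged invalid and return all-zero coefficients rather than erroring.
#'
#' @param signal numeric vector, one value per scheme volume.
#' @param design matrix from [rsi_design()] (its `"blocks"` attribute is
#'   used to partition coefficients).
#' @param scheme the [acquisition_scheme()] the design was built from
#'   (needed to locate b = 0 rows for the validity check).
#' @param ridge_lambda Tikhonov weight relative to the largest singular
#'   value of the design (default 1e-6; 0 means exact pseudoinverse).
#' @return An object of class `rsi_coefficients`: list with `restricted`,
#'   `hindered`, `free`, `fit_residual_norm`, `valid`.
#' @export
fit_rsi_voxel <- function(signal, design, scheme, ridge_lambda = 1e-6) {
  if (length(signal) != nrow(design)) {
    stop("signal length [", length(signal),
         "] does not match design rows [", nrow(design), "]")
  }
  solver <- rsi_solver(design, ridge_lambda)
  fit_rsi_voxel_solved(signal, design, solver, scheme)
}

# inner kernel shared with fit_rsi_volume(); solver precomputed
fit_rsi_voxel_solved <- function(signal, design, solver, scheme) {
  blocks <- attr(design, "blocks")
  b0 <- scheme$bvals == 0
  bad <- any(!is.finite(signal)) || !any(b0) || mean(signal[b0]) <= 0
  if (bad) {
    x <- numeric(ncol(design))
    res <- NA_real_
  } else {
    x <- drop(solver %*% signal)
    res <- sqrt(sum((signal - drop(design %*% x))^2))
  }
  structure(
    list(restricted = x[blocks$restricted],
         hindered = x[blocks$hindered],
         free = x[blocks$free],
         fit_residual_norm = res,
         valid = !bad),
    class = "rsi_coefficients"
  )
}

#' Normalized RSI signal-fraction metrics
#'
#' Normalizes the fitted compartment coefficients to signal fractions.
#' With `N` the Euclidean norm of the full coefficient vector:
#' RNI = |restricted l=0| / N, RND = ||restricted l in 2,4|| / N, and HNI /
#' HND analogously for the hindered compartment; FNI = |free| / N. Totals
#' combine the isotropic and directional parts either additively
#' (`norm_mode = "sum"`, the default: RNT = RNI + RND) or in quadrature
#' (`norm_mode = "euclidean"`: RNT = sqrt(RNI^2 + RND^2)). All fractions
#' are clipped to \[0, 1\]. Zero-norm or invalid coefficients yield zero
#' metrics flagged invalid.
#'
#' @param coeffs an `rsi_coefficients` object from [fit_rsi_voxel()].
#' @param norm_mode `"sum"` or `"euclidean"`.
#' @return An object of class `rsi_metrics`: list with `rni`, `rnd`,
#'   `rnt`, `hni`, `hnd`, `hnt`, `fni`, `norm_mode`, `valid`.
#' @export
rsi_metrics <- function(coeffs, norm_mode = c("sum", "euclidean")) {
  norm_mode <- match.arg(norm_mode)
  stopifnot(inherits(coeffs, "rsi_coefficients"))
  x <- c(coeffs$restricted, coeffs$hindered, coeffs$free)
  N <- sqrt(sum(x^2))
  if (!coeffs$valid || !is.finite(N) || N == 0) {
    m <- list(rni = 0, rnd = 0, rnt = 0, hni = 0, hnd = 0, hnt = 0, fni = 0,
              norm_mode = norm_mode, valid = FALSE)
    return(structure(m, class = "rsi_metrics"))
  }
  clip01 <- function(v) pmin(1, pmax(0, v))
  rni <- clip01(abs(coeffs$restricted[1]) / N)
  rnd <- clip01(sqrt(sum(coeffs$restricted[-1]^2)) / N)
  hni <- clip01(abs(coeffs$hindered[1]) / N)
  hnd <- clip01(sqrt(sum(coeffs$hindered[-1]^2)) / N)
  fni <- clip01(abs(coeffs$free) / N)
  if (norm_mode == "sum") {
    rnt <- rni + rnd
    hnt <- hni + hnd
  } else {
    rnt <- sqrt(rni^2 + rnd^2)
    hnt <- sqrt(hni^2 + hnd^2)
  }
  structure(
    list(rni = rni, rnd = rnd, rnt = clip01(rnt),
         hni = hni, hnd = hnd, hnt = clip01(hnt),
         fni = fni, norm_mode = norm_mode, valid = TRUE),
    class = "rsi_metrics"
  )
}

#' Fit RSI metric maps over a volume
#'
#' Applies [fit_rsi_voxel()] and [rsi_metrics()] to every voxel inside the
#' mask of a 4D diffusion-weighted volume. Voxels outside the mask, and
#' voxels flagged invalid by the fit, are `NaN` in every output map. The
#' computation is deterministic given its inputs.
#'
#' @param dwi 4D numeric array, 4th dimension matching the scheme length.
#' @param scheme an [acquisition_scheme()].
#' @param model an [compartment_model()].
#' @param mask 3D logical array matching the spatial dimensions of `dwi`;
#'   `NULL` fits every voxel.
#' @param norm_mode,ridge_lambda passed to [rsi_metrics()] /
#'   [fit_rsi_voxel()].
#' @return Named list of 3D arrays: `rni`, `rnd`, `rnt`, `hni`, `hnd`,
#'   `hnt`, `fni`.
#' @export
fit_rsi_volume <- function(dwi, scheme, model = compartment_model(),
                           mask = NULL, norm_mode = "sum",
                           ridge_lambda = 1e-6) {
  d <- dim(dwi)
  if (length(d) != 4) stop("dwi must be a 4D array")
  if (d[4] != length(scheme$bvals)) {
    stop("dwi has ", d[4], " volumes but the scheme has ",
         length(scheme$bvals))
  }
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!all(dim(mask) == d[1:3])) stop("mask dimensions do not match dwi")
  design <- rsi_design(scheme, model)
  solver <- rsi_solver(design, ridge_lambda)
  sig <- matrix(dwi, prod(d[1:3]), d[4])
  idx <- which(as.logical(mask))
  metric_names <- c("rni", "rnd", "rnt", "hni", "hnd", "hnt", "fni")
  maps <- matrix(NaN, prod(d[1:3]), length(metric_names),
                 dimnames = list(NULL, metric_names))
  for (v in idx) {
    co <- fit_rsi_voxel_solved(sig[v, ], design, solver, scheme)
    m <- rsi_metrics(co, norm_mode)
    if (m$valid) maps[v, ] <- unlist(m[metric_names])
  }
  out <- lapply(metric_names, function(nm) array(maps[, nm], d[1:3]))
  names(out) <- metric_names
  out
}
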