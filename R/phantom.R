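#' Ground-truth compartment mixture for one phantom voxel
#'
#' @param restricted_fraction,hindered_fraction,free_fraction non-negative
#'   signal weights (their sum is the b = 0 signal).
#' @param fiber_direction unit 3-vector orienting the restricted and
#'   hindered tensors.
#' @param dispersion non-negative orientation-dispersion parameter for the
#'   restricted/hindered axis: 0 is an ideal stick (no dispersion); values
#'   > 0 average the kernel over a Watson-style axial distribution with
#'   concentration `1/dispersion`.
#' @return Object of class `voxel_truth`.
#' @export
voxel_truth <- function(restricted_fraction = 0,
                        hindered_fraction = 0,
                        free_fraction = 0,
                        fiber_direction = c(0, 0, 1),
                        dispersion = 0) {
  fr <- c(restricted_fraction, hindered_fraction, free_fraction)
  if (any(!is.finite(fr)) || any(fr < 0)) {
    stop("compartment fractions must be finite and non-negative")
  }
  if (dispersion < 0) stop("dispersion must be >= 0")
  nrm <- sqrt(sum(fiber_direction^2))
  if (nrm < 1e-12) stop("fiber_direction must be a non-zero vector")
  structure(
    list(restricted_fraction = restricted_fraction,
         hindered_fraction = hindered_fraction,
         free_fraction = free_fraction,
         fiber_direction = fiber_direction / nrm,
         dispersion = dispersion),
    class = "voxel_truth"
  )
}

# axially symmetric tensor attenuation for gradients g (rows) about axis mu
tensor_attenuation <- function(bvals, bvecs, mu, dax, drad, dispersion = 0) {
  if (dispersion == 0) {
    cu2 <- drop(bvecs %*% mu)^2
    return(exp(-bvals * (drad + (dax - drad) * cu2)))
  }
  # Watson-style axial average: fixed deterministic sphere grid weighted by
  # exp(kappa * (mu . v)^2), kappa = 1 / dispersion
  grid <- fibonacci_sphere(200)
  kappa <- 1 / dispersion
  w <- exp(kappa * (drop(grid %*% mu)^2 - 1))   # -1 rescale for stability
  w <- w / sum(w)
  cu2 <- (bvecs %*% t(grid))^2                  # n_vols x n_grid
  att <- exp(-outer(bvals, rep(1, nrow(grid))) *
               (drad + (dax - drad) * cu2))
  drop(att %*% w)
}

#' Simulate a multi-shell DWI signal from a known mixture
#'
#' Clean signal is the weighted sum of the three compartment signals:
#' restricted and hindered as axially symmetric tensors around
#' `fiber_direction` (optionally Watson-dispersed), free water isotropic.
#' With finite `snr`, Rician noise is applied as
#' `sqrt((S + e1)^2 + e2^2)` with `e ~ Normal(0, sigma^2)` and
#' `sigma = S(b=0) / snr`.
#'
#' @param truth a [voxel_truth()].
#' @param scheme an [acquisition_scheme()].
#' @param model an [compartment_model()].
#' @param snr signal-to-noise ratio at b = 0; `Inf` for noiseless.
#' @param seed integer seed for the noise draws (ignored when `snr = Inf`).
#' @return numeric signal vector, one value per scheme volume.
#' @export
simulate_dwi_signal <- function(truth, scheme, model = compartment_model(),
                                snr = Inf, seed = NULL) {
  stopifnot(inherits(truth, "voxel_truth"), inherits(scheme, "rsi_scheme"))
  if (!(snr > 0)) stop("snr must be > 0 (Inf for noiseless)")
  b <- scheme$bvals
  g <- scheme$bvecs
  s <- truth$restricted_fraction *
    tensor_attenuation(b, g, truth$fiber_direction,
                       model$restricted_axial_diffusivity,
                       model$restricted_radial_diffusivity,
                       truth$dispersion) +
    truth$hindered_fraction *
    tensor_attenuation(b, g, truth$fiber_direction,
                       model$hindered_axial_diffusivity,
                       model$hindered_radial_diffusivity,
                       truth$dispersion) +
    truth$free_fraction * exp(-b * model$free_diffusivity)
  if (is.finite(snr)) {
    s0 <- truth$restricted_fraction + truth$hindered_fraction +
      truth$free_fraction
    sigma <- s0 / snr
    noise <- function() {
      e1 <- stats::rnorm(length(s), 0, sigma)
      e2 <- stats::rnorm(length(s), 0, sigma)
      sqrt((s + e1)^2 + e2^2)
    }
    s <- if (is.null(seed)) noise() else withr::with_seed(as.integer(seed), noise())
  }
  as.numeric(s)
}

#' Signal synthesized from known spherical-harmonic coefficients
#'
#' Evaluates the linear forward model `design %*% coefficients`: the exact
#' signal whose deconvolution should return the generating coefficients.
#' Used for round-trip validation of the fitting path.
#'
#' @param coefficients full coefficient vector (restricted block, hindered
#'   block, free scalar) or an `rsi_coefficients` object.
#' @param design matrix from [rsi_design()].
#' @return numeric signal vector.
#' @export
signal_from_coefficients <- function(coefficients, design) {
  if (inherits(coefficients, "rsi_coefficients")) {
    coefficients <- c(coefficients$restricted, coefficients$hindered,
                      coefficients$free)
  }
  if (length(coefficients) != ncol(design)) {
    stop("coefficient length does not match design columns")
  }
  drop(design %*% coefficients)
}

#' Build a piecewise-constant 4D DWI phantom
#'
#' Fills a labelled volume with simulated signals: every voxel of region
#' `k` carries the signal of `truths[[k]]` (plus independent Rician noise
#' when `snr` is finite). Label 0 voxels are background zeros.
#'
#' @param labels 3D integer array of region labels (0 = background).
#' @param truths list of [voxel_truth()], one per region label 1..K.
#' @param scheme,model,snr as in [simulate_dwi_signal()].
#' @param seed integer seed; voxel noise is drawn reproducibly from it.
#' @return 4D array `c(dim(labels), n_volumes)`.
#' @export
simulate_dwi_volume <- function(labels, truths, scheme,
                                model = compartment_model(),
                                snr = Inf, seed = 1L) {
  labels <- as.array(labels)
  stopifnot(length(dim(labels)) == 3)
  nvol <- length(scheme$bvals)
  clean <- lapply(truths, simulate_dwi_signal, scheme = scheme,
                  model = model, snr = Inf)
  sig <- matrix(0, length(labels), nvol)
  for (k in seq_along(truths)) {
    rows <- which(labels == k)
    if (length(rows)) sig[rows, ] <- rep(clean[[k]], each = length(rows))
  }
  if (is.finite(snr)) {
    s0 <- vapply(truths, function(tr) {
      tr$restricted_fraction + tr$hindered_fraction + tr$free_fraction
    }, numeric(1))
    sig <- withr::with_seed(as.integer(seed), {
      out <- sig
      for (k in seq_along(truths)) {
        rows <- which(labels == k)
        if (!length(rows)) next
        sigma <- s0[k] / snr
        e1 <- matrix(stats::rnorm(length(rows) * nvol, 0, sigma),
                     length(rows), nvol)
        e2 <- matrix(stats::rnorm(length(rows) * nvol, 0, sigma),
                     length(rows), nvol)
        out[rows, ] <- sqrt((sig[rows, , drop = FALSE] + e1)^2 + e2^2)
      }
      out
    })
  }
  array(sig, c(dim(labels), nvol))
}
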