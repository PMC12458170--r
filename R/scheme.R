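#' Multi-shell diffusion acquisition scheme
#'
#' An acquisition scheme pairs one b-value (s/mm^2) with one unit gradient
#' direction per acquired volume. Directions on b = 0 rows are arbitrary and
#' stored as the z axis.
#'
#' @param bvals numeric vector of b-values (s/mm^2, non-negative).
#' @param bvecs numeric matrix with one row per volume and three columns.
#'   Rows with b > 0 must have Euclidean norm within 1e-6 of 1.
#' @return An object of class `rsi_scheme`: a list with `bvals`, `bvecs`
#'   (n x 3 matrix) and `shell_index` (integer shell label per volume,
#'   shells numbered by increasing b-value, b = 0 is shell 0).
#' @export
acquisition_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (length(bvals) != nrow(bvecs)) {
    stop("length(bvals) [", length(bvals), "] must equal nrow(bvecs) [",
         nrow(bvecs), "]")
  }
  if (ncol(bvecs) != 3L) stop("bvecs must have three columns")
  if (any(!is.finite(bvals)) || any(bvals < 0)) {
    stop("b-values must be finite and non-negative")
  }
  dwi <- bvals > 0
  if (any(dwi)) {
    nrm <- sqrt(rowSums(bvecs[dwi, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      stop("non-b0 gradient directions must be unit vectors (max |norm - 1| = ",
           format(max(abs(nrm - 1))), ")")
    }
  }
  bvecs[!dwi, ] <- rep(c(0, 0, 1), each = sum(!dwi))
  shells <- sort(unique(bvals[dwi]))
  shell_index <- integer(length(bvals))
  shell_index[dwi] <- match(bvals[dwi], shells)
  structure(
    list(bvals = bvals, bvecs = bvecs, shell_index = shell_index),
    class = "rsi_scheme"
  )
}

#' @export
print.rsi_scheme <- function(x, ...) {
  cat("<rsi_scheme>", length(x$bvals), "volumes\n")
  tab <- table(x$bvals)
  for (b in names(tab)) cat("  b =", b, ":", tab[[b]], "volumes\n")
  invisible(x)
}

#' Near-uniform points on the unit sphere
#'
#' Deterministic Fibonacci-lattice layout, optionally rotated about the z
#' axis by a seed-derived angle so that repeated shells do not share
#' directions.
#'
#' @param n number of points.
#' @param rotation rotation angle about z (radians).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n, rotation = 0) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  golden <- pi * (1 + sqrt(5))
  phi <- golden * i + rotation
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Build the study's multi-shell HARDI scheme
#'
#' The default protocol is 6 b = 0 volumes plus 96 diffusion directions
#' spread over four shells: b = 500 (6 directions), 1000 (15), 2000 (15) and
#' 3000 s/mm^2 (60), i.e. 102 volumes in total. Per-shell directions come
#' from a Fibonacci-sphere layout; the seed only rotates each shell's
#' lattice so the scheme is fully deterministic per seed.
#'
#' @param seed integer; rotates the per-shell direction lattices.
#' @param shell_bvals b-value of each diffusion shell (s/mm^2).
#' @param shell_ndirs number of directions per shell.
#' @param n_b0 number of b = 0 volumes.
#' @return An [acquisition_scheme()] object.
#' @export
build_hardi_scheme <- function(seed = 1L,
                               shell_bvals = c(500, 1000, 2000, 3000),
                               shell_ndirs = c(6L, 15L, 15L, 60L),
                               n_b0 = 6L) {
  stopifnot(length(shell_bvals) == length(shell_ndirs))
  rot <- withr::with_seed(as.integer(seed),
                          stats::runif(length(shell_bvals), 0, 2 * pi))
  bvals <- rep(0, n_b0)
  bvecs <- matrix(rep(c(0, 0, 1), each = n_b0), ncol = 3)
  for (k in seq_along(shell_bvals)) {
    bvals <- c(bvals, rep(shell_bvals[k], shell_ndirs[k]))
    bvecs <- rbind(bvecs, fibonacci_sphere(shell_ndirs[k], rot[k]))
  }
  acquisition_scheme(bvals, bvecs)
}

#' Three-compartment RSI tissue model
#'
#' Fixed-diffusivity compartments: restricted and hindered diffusion are
#' axially symmetric tensors expanded in even-order spherical harmonics up
#' to `lmax`; free water is isotropic (order 0 only). Defaults follow the
#' usual pediatric multi-shell RSI parameterization: axial diffusivity
#' 1e-3 mm^2/s for both tissue compartments, radial diffusivity 0 for
#' restricted and 0.9e-3 mm^2/s for hindered, free diffusivity 3e-3 mm^2/s,
#' fourth-order harmonics for the tissue compartments.
#'
#' @param restricted_axial_diffusivity,restricted_radial_diffusivity
#'   restricted-compartment diffusivities (mm^2/s).
#' @param hindered_axial_diffusivity,hindered_radial_diffusivity
#'   hindered-compartment diffusivities (mm^2/s).
#' @param free_diffusivity free-water diffusivity (mm^2/s).
#' @param lmax_restricted,lmax_hindered maximum (even) spherical-harmonic
#'   order for the two anisotropic compartments.
#' @return An object of class `rsi_model`.
#' @export
compartment_model <- function(restricted_axial_diffusivity = 1e-3,
                              restricted_radial_diffusivity = 0,
                              hindered_axial_diffusivity = 1e-3,
                              hindered_radial_diffusivity = 0.9e-3,
                              free_diffusivity = 3e-3,
                              lmax_restricted = 4L,
                              lmax_hindered = 4L) {
  ds <- c(restricted_axial_diffusivity, restricted_radial_diffusivity,
          hindered_axial_diffusivity, hindered_radial_diffusivity,
          free_diffusivity)
  if (any(!is.finite(ds)) || any(ds < 0)) {
    stop("diffusivities must be finite and non-negative")
  }
  for (l in c(lmax_restricted, lmax_hindered)) {
    if (l < 0 || l %% 2 != 0) stop("lmax must be an even non-negative integer")
  }
  structure(
    list(restricted_axial_diffusivity = restricted_axial_diffusivity,
         restricted_radial_diffusivity = restricted_radial_diffusivity,
         hindered_axial_diffusivity = hindered_axial_diffusivity,
         hindered_radial_diffusivity = hindered_radial_diffusivity,
         free_diffusivity = free_diffusivity,
         lmax_restricted = as.integer(lmax_restricted),
         lmax_hindered = as.integer(lmax_hindered),
         lmax_free = 0L),
    class = "rsi_model"
  )
}
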