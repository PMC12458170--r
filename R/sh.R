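#' Real even-order spherical-harmonic basis
#'
#' Evaluates the real, symmetric (even-order only) spherical-harmonic basis
#' in the modified-real convention used throughout diffusion MRI:
#' for order l and degree m,
#' `Y_{l,0}` is the standard real harmonic, `Y_{l,m>0} = sqrt(2) N_{lm}
#' P_l^m(cos theta) cos(m phi)` and `Y_{l,m<0} = sqrt(2) N_{l|m|}
#' P_l^{|m|}(cos theta) sin(|m| phi)`, with the Condon-Shortley phase
#' carried by the associated Legendre functions. Columns are ordered by l
#' ascending, and within each l by m ascending (-l ... l), so lmax = 4
#' gives 1 + 5 + 9 = 15 columns.
#'
#' @param directions n x 3 matrix of unit vectors (rows).
#' @param lmax maximum even order (0, 2, 4, ...).
#' @return n x n_coef matrix of basis values; the basis is orthonormal
#'   under the uniform measure on the sphere.
#' @export
sh_basis <- function(directions, lmax) {
  directions <- matrix(as.numeric(directions), ncol = 3)
  if (length(lmax) != 1 || lmax < 0 || lmax %% 2 != 0) {
    stop("lmax must be a single even non-negative integer")
  }
  nrm <- sqrt(rowSums(directions^2))
  if (any(nrm < 1e-12)) stop("directions must be non-zero vectors")
  directions <- directions / nrm
  ct <- pmin(1, pmax(-1, directions[, 3]))
  phi <- atan2(directions[, 2], directions[, 1])
  n <- nrow(directions)
  cols <- vector("list", sh_n_coef(lmax))
  k <- 0L
  for (l in seq(0, lmax, by = 2)) {
    P <- pracma::legendre(l, ct)            # (l+1) x n, rows m = 0..l
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    for (m in seq(-l, l)) {
      am <- abs(m)
      N <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      v <- N * P[am + 1, ]
      if (m < 0) v <- sqrt(2) * v * sin(am * phi)
      if (m > 0) v <- sqrt(2) * v * cos(am * phi)
      k <- k + 1L
      cols[[k]] <- v
    }
  }
  out <- do.call(cbind, cols)
  dimnames(out) <- list(NULL, sh_index(lmax)$name)
  out
}

# number of even-order real SH coefficients up to lmax
sh_n_coef <- function(lmax) {
  sum(2 * seq(0, lmax, by = 2) + 1)
}

# (l, m) index table for the even-order basis, column order of sh_basis()
sh_index <- function(lmax) {
  l <- unlist(lapply(seq(0, lmax, by = 2), function(l) rep(l, 2 * l + 1)))
  m <- unlist(lapply(seq(0, lmax, by = 2), function(l) seq(-l, l)))
  data.frame(l = l, m = m, name = sprintf("l%dm%+d", l, m))
}

#' Rotational harmonic response of a compartment signal kernel
#'
#' For the axially symmetric tensor signal
#' `S(theta) = exp(-b (D_rad + (D_ax - D_rad) cos^2 theta))`
#' the order-l response is the Legendre moment
#' `r_l = 1/2 Integral_{-1}^{1} S(u) P_l(u) du`,
#' evaluated by Gauss-Legendre quadrature. At l = 0 this is the spherical
#' mean of the kernel; at b = 0 it is 1 for l = 0 and 0 for l > 0. The
#' isotropic free-water compartment has response `exp(-b D_free)` at l = 0
#' only.
#'
#' @param bval b-value (s/mm^2, non-negative scalar).
#' @param model an [compartment_model()] object.
#' @param compartment one of `"restricted"`, `"hindered"`, `"free"`.
#' @param l even harmonic order, at most the compartment's lmax.
#' @param n_nodes number of Gauss-Legendre nodes (>= 64 gives < 1e-12
#'   error for b * D <= 9).
#' @return scalar response.
#' @export
compartment_response <- function(bval, model,
                                 compartment = c("restricted", "hindered", "free"),
                                 l = 0L, n_nodes = 64L) {
  compartment <- match.arg(compartment)
  if (length(bval) != 1 || !is.finite(bval) || bval < 0) {
    stop("bval must be a single non-negative number")
  }
  if (l %% 2 != 0 || l < 0) stop("harmonic order l must be even and >= 0")
  lmax <- switch(compartment,
                 restricted = model$lmax_restricted,
                 hindered = model$lmax_hindered,
                 free = model$lmax_free)
  if (l > lmax) {
    stop("order l = ", l, " exceeds lmax = ", lmax, " for the ",
         compartment, " compartment")
  }
  if (compartment == "free") {
    return(exp(-bval * model$free_diffusivity))
  }
  dax <- switch(compartment,
                restricted = model$restricted_axial_diffusivity,
                hindered = model$hindered_axial_diffusivity)
  drad <- switch(compartment,
                 restricted = model$restricted_radial_diffusivity,
                 hindered = model$hindered_radial_diffusivity)
  gl <- pracma::gaussLegendre(n_nodes, -1, 1)
  s <- exp(-bval * (drad + (dax - drad) * gl$x^2))
  pl <- if (l == 0) rep(1, n_nodes) else pracma::legendre(l, gl$x)[1, ]
  0.5 * sum(gl$w * s * pl)
}
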