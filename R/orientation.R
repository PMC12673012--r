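# Euler-angle orientation sampling and Mueller-matrix averaging for
# free-floating cells.  Convention: z-y-z intrinsic Euler rotation
# R = Rz(alpha) Ry(beta) Rz(gamma), body axes to laboratory axes; angles
# sampled uniformly in the angle over alpha, gamma in [0, 360) and beta in
# [0, 180].

#' Euler rotation matrix
#'
#' @param alpha,beta,gamma Euler angles in degrees (z-y-z convention)
#' @return 3x3 rotation matrix (body to lab)
#' @export
euler_matrix <- function(alpha, beta, gamma) {
  rz <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  ry <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  }
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

#' Orientation sampling for axisymmetric cells
#'
#' Axisymmetric shapes (biconcave disc, morph family) are insensitive to
#' the spin angle gamma, so n orientations are drawn over the polar angle
#' beta in [0, 180] (and, by default, the azimuth alpha as well: with a
#' fixed detection plane, tilting the cell axis only within that plane
#' keeps the scatterer mirror-symmetric about it, which forces the
#' cross-polarization amplitudes -- and hence K1 -- to vanish identically;
#' a free-floating cell samples the azimuth too).
#'
#' @param n number of orientations (default 30)
#' @param seed RNG seed
#' @param azimuth sample alpha uniformly over [0, 360) (default TRUE);
#'   FALSE restricts the axis to the detection plane (alpha = 0)
#' @return data.frame with columns alpha, beta, gamma (degrees)
#' @export
sample_axisymmetric <- function(n = 30, seed = NULL, azimuth = TRUE) {
  stopifnot(n >= 1)
  with_seed(seed, {
    beta <- stats::runif(n, 0, 180)
    alpha <- if (azimuth) stats::runif(n, 0, 360) else rep(0, n)
    data.frame(alpha = alpha, beta = beta, gamma = 0)
  })
}

#' Full-space orientation sampling
#'
#' For shapes without symmetry (spiculated cells): a Cartesian product of
#' \code{n_per_angle} random values per Euler angle, giving
#' \code{n_per_angle^3} orientations (125 at the default 5).
#'
#' @param n_per_angle random values per Euler angle (default 5)
#' @param seed RNG seed
#' @return data.frame with columns alpha, beta, gamma (degrees)
#' @export
sample_full <- function(n_per_angle = 5, seed = NULL) {
  stopifnot(n_per_angle >= 1)
  with_seed(seed, {
    a <- stats::runif(n_per_angle, 0, 360)
    b <- stats::runif(n_per_angle, 0, 180)
    g <- stats::runif(n_per_angle, 0, 360)
    expand.grid(alpha = a, beta = b, gamma = g)
  })
}

#' Average raw Mueller matrices over orientations
#'
#' Element-wise arithmetic mean of unnormalized matrices; normalization is
#' applied after averaging, matching an ensemble measurement.
#'
#' @param mms non-empty list of 4x4 matrices
#' @return 4x4 matrix
#' @export
average_mm <- function(mms) {
  if (!length(mms)) stop("cannot average an empty list of Mueller matrices")
  Reduce(`+`, mms) / length(mms)
}
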