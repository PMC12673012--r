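# Forward/inverse model of the dual-angle Mueller-matrix polarimeter
# detection chain: four-quadrant PSA Stokes reconstruction, Mueller-matrix
# recovery from sequences of polarization states, and the
# microsphere-based system-error calibration.

#' Stokes vector from four-quadrant PSA voltages
#'
#' The analyzer splits the beam into four channels: 0-degree, 45-degree and
#' 90-degree linear polarizers plus a circular channel (quarter-wave plate
#' + polarizer, left circular).  The Stokes vector follows as
#' I = s0 + s90, Q = s0 - s90, U = 2 s45 - s0 - s90, V = s0 + s90 - 2 sL.
#'
#' @param s0,s45,s90,sL channel voltages (arbitrary units); alternatively
#'   pass a single length-4 vector, or a 4 x n matrix with one channel
#'   per row (the layout \code{\link{synth_quadrants}} produces), as
#'   \code{s0}
#' @return numeric vector (I, Q, U, V), or a 4 x n matrix of column Stokes
#'   vectors for matrix input
#' @export
stokes_from_quadrants <- function(s0, s45 = NULL, s90 = NULL, sL = NULL) {
  if (is.null(s45)) {
    q <- if (is.matrix(s0)) s0 else matrix(s0, nrow = 4)
    s45 <- q[2, ]; s90 <- q[3, ]; sL <- q[4, ]; s0 <- q[1, ]
  }
  out <- rbind(I = s0 + s90,
               Q = s0 - s90,
               U = 2 * s45 - s0 - s90,
               V = s0 + s90 - 2 * sL)
  if (ncol(out) == 1) drop(out) else out
}

# inverse of the quadrant map (exact at zero noise)
quadrants_from_stokes <- function(S) {
  S <- if (is.matrix(S)) S else matrix(S, nrow = 4)
  rbind(s0 = (S[1, ] + S[2, ]) / 2,
        s45 = (S[1, ] + S[3, ]) / 2,
        s90 = (S[1, ] - S[2, ]) / 2,
        sL = (S[1, ] - S[4, ]) / 2)
}

#' Canonical polarization-state set
#'
#' Six states spanning the Poincare sphere -- H, V, +45, right-circular,
#' -45, left-circular -- ordered so that every prefix of length >= 4 has
#' full rank (the first four already span all Stokes dimensions).
#'
#' @param n number of states (first n columns of the canonical six; for
#'   other sets pass your own matrix)
#' @return 4 x n matrix of Stokes column vectors
#' @export
sop_states <- function(n = 6) {
  S <- cbind(c(1, 1, 0, 0), c(1, -1, 0, 0), c(1, 0, 1, 0),
             c(1, 0, 0, 1), c(1, 0, -1, 0), c(1, 0, 0, -1))
  stopifnot(n >= 1, n <= 6)
  S[, seq_len(n), drop = FALSE]
}

#' Recover a Mueller matrix from incident/scattered Stokes pairs
#'
#' Least-squares solution \code{MM = S_out %*% pinv(S_in)} via the
#' Moore-Penrose pseudoinverse; exact when \code{S_in} has rank 4.
#'
#' @param S_in 4 x N matrix of incident Stokes columns (N >= 4, rank 4)
#' @param S_out 4 x N matrix of measured scattered Stokes columns
#' @return 4 x 4 Mueller matrix
#' @export
mm_from_stokes <- function(S_in, S_out) {
  stopifnot(is.matrix(S_in), is.matrix(S_out), nrow(S_in) == 4,
            nrow(S_out) == 4, ncol(S_in) == ncol(S_out))
  if (ncol(S_in) < 4)
    stop("Mueller recovery needs at least 4 polarization states, got ",
         ncol(S_in))
  if (qr(S_in)$rank < 4)
    stop("incident Stokes set is rank-deficient (rank ",
         qr(S_in)$rank, " < 4): states do not span the Poincare sphere")
  S_out %*% MASS::ginv(S_in)
}

#' Calibration model of the detection chain
#'
#' System error model \code{MM_r = Mp MM_m - Ms}: \code{Mp} collects the
#' multiplicative polarization bias of the optical train, \code{Ms} the
#' additive non-polarization error; \code{MM_r} is the Mie-theory
#' reference of the standard microspheres, \code{MM_m} the measured
#' matrix.
#'
#' @param Mp,Ms 4 x 4 matrices (Mp invertible)
#' @return object of class \code{calibration_model}
#' @export
calibration_model <- function(Mp = diag(4), Ms = matrix(0, 4, 4)) {
  stopifnot(all(dim(Mp) == 4), all(dim(Ms) == 4))
  if (abs(det(Mp)) < 1e-12) stop("Mp must be invertible")
  structure(list(Mp = Mp, Ms = Ms), class = "calibration_model")
}

#' Fit the calibration model from microsphere standards
#'
#' Joint linear least squares for (Mp, Ms) over pairs of measured and
#' reference matrices, minimizing \code{sum || Mp MM_m - Ms - MM_r ||_F^2}.
#' One pair leaves the 32 unknowns under-determined (16 equations); at
#' least two structurally independent pairs are required.
#'
#' @param measured list of measured 4 x 4 matrices
#' @param reference list of Mie-reference 4 x 4 matrices (same length)
#' @return \code{calibration_model} with an added \code{residual} element
#'   (root-mean-square fit residual)
#' @export
fit_calibration <- function(measured, reference) {
  stopifnot(is.list(measured), is.list(reference),
            length(measured) == length(reference))
  np <- length(measured)
  if (np < 2)
    stop("under-determined calibration: ", 16 * np,
         " equations for 32 unknowns; need at least 2 standards")
  # unknown theta = c(vec(Mp), vec(Ms)) with vec() column-major
  # row for element (i,j) of pair p:  sum_k Mp[i,k] Mm[k,j] - Ms[i,j]
  X <- matrix(0, 16 * np, 32)
  y <- numeric(16 * np)
  r <- 0L
  for (p in seq_len(np)) {
    Mm <- measured[[p]]; Mr <- reference[[p]]
    for (j in 1:4) for (i in 1:4) {
      r <- r + 1L
      X[r, (0:3) * 4 + i] <- Mm[, j]        # Mp[i, k] entries
      X[r, 16 + (j - 1) * 4 + i] <- -1      # -Ms[i, j]
      y[r] <- Mr[i, j]
    }
  }
  q <- qr(X)
  if (q$rank < 32)
    stop("under-determined calibration: standards are not structurally ",
         "independent (design rank ", q$rank, " < 32)")
  theta <- qr.coef(q, y)
  Mp <- matrix(theta[1:16], 4, 4)
  Ms <- matrix(theta[17:32], 4, 4)
  cal <- calibration_model(Mp, Ms)
  cal$residual <- sqrt(mean((X %*% theta - y)^2))
  cal
}

#' Apply a calibration model to a measured Mueller matrix
#'
#' @param cal \code{calibration_model}
#' @param mm_measured 4 x 4 measured matrix
#' @return corrected 4 x 4 matrix \code{Mp mm - Ms}
#' @export
apply_calibration <- function(cal, mm_measured) {
  stopifnot(inherits(cal, "calibration_model"), all(dim(mm_measured) == 4))
  cal$Mp %*% mm_measured - cal$Ms
}

# forward error model: what the instrument measures for a true matrix
distort_mm <- function(cal, mm_true) {
  solve(cal$Mp, mm_true + cal$Ms)
}

#' Synthesize four-quadrant voltage sequences
#'
#' Forward model of one cell transit: the true Mueller matrix maps each
#' incident state to a scattered Stokes vector, which is inverted to the
#' four PSA channel voltages; optional additive Gaussian noise emulates
#' PMT/electronic noise.  Zero noise round-trips exactly through
#' \code{\link{stokes_from_quadrants}}.
#'
#' @param mm_true 4 x 4 Mueller matrix
#' @param S_in 4 x N incident Stokes columns (default the canonical six)
#' @param noise_sd Gaussian noise standard deviation (voltage units)
#' @param seed RNG seed
#' @return 4 x N matrix of channel voltages (rows s0, s45, s90, sL)
#' @export
synth_quadrants <- function(mm_true, S_in = sop_states(), noise_sd = 0,
                            seed = NULL) {
  stopifnot(all(dim(mm_true) == 4), noise_sd >= 0)
  q <- quadrants_from_stokes(mm_true %*% S_in)
  if (noise_sd > 0)
    q <- q + with_seed(seed, matrix(stats::rnorm(length(q), 0, noise_sd),
                                    nrow(q), ncol(q)))
  q
}
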