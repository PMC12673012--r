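# Mie theory for homogeneous spheres: exact partial-wave amplitudes and
# Mueller matrices.  Serves as the validation oracle for the DDA solver and
# as the reference model for microsphere calibration.
#
# Conventions (Bohren & Huffman): time factor exp(-i*omega*t); amplitude
# matrix defined through E_sca = exp(ikr)/(-ikr) * S * E_inc in the
# (parallel, perpendicular) scattering-plane basis; for a sphere
# S = diag(S2, S1).

#' Mie input parameters
#'
#' @param x size parameter, k * radius with k the wavenumber in the
#'   surrounding medium (dimensionless, > 0)
#' @param m complex refractive index of the sphere relative to the medium
#' @return object of class \code{mie_input}
#' @export
mie_input <- function(x, m) {
  stopifnot(is.numeric(x), length(x) == 1L, x > 0, length(m) == 1L)
  structure(list(x = x, m = as.complex(m)), class = "mie_input")
}

# Wiscombe series truncation
mie_nmax <- function(x) ceiling(x + 4 * x^(1 / 3) + 2)

# Mie expansion coefficients a_n, b_n, n = 1..nmax.
# Logarithmic derivative D_n(mx) by downward recurrence (stable), Riccati-
# Bessel psi_n(x), chi_n(x) by upward recurrence (stable for n ~ x + O(x^1/3)).
mie_ab <- function(x, m) {
  if (x > 2000) stop("size parameter too large: Mie series would overflow")
  nmax <- mie_nmax(x)
  mx <- m * x
  nstart <- nmax + 15L
  D <- complex(nstart + 1L)            # D[n + 1] = D_n(mx)
  for (n in nstart:1L) {
    rn <- n / mx
    D[n] <- rn - 1 / (D[n + 1L] + rn)  # gives D_{n-1} stored at index n
  }
  D <- D[seq_len(nmax) + 1L]           # D_1..D_nmax  (index shift: D[k]=D_k)
  # psi_{-1} = cos x, psi_0 = sin x ; chi_{-1} = -sin x, chi_0 = cos x
  psi <- numeric(nmax + 1L)
  chi <- numeric(nmax + 1L)
  psi_m1 <- cos(x); psi[1] <- sin(x)
  chi_m1 <- -sin(x); chi[1] <- cos(x)
  for (n in 1:nmax) {
    psi[n + 1L] <- (2 * n - 1) / x * psi[n] - if (n == 1) psi_m1 else psi[n - 1L]
    chi[n + 1L] <- (2 * n - 1) / x * chi[n] - if (n == 1) chi_m1 else chi[n - 1L]
  }
  xi <- psi - 1i * chi
  n <- seq_len(nmax)
  psin <- psi[n + 1L]; psin1 <- psi[n]
  xin <- xi[n + 1L]; xin1 <- xi[n]
  ta <- D / m + n / x
  tb <- D * m + n / x
  a <- (ta * psin - psin1) / (ta * xin - xin1)
  b <- (tb * psin - psin1) / (tb * xin - xin1)
  list(a = a, b = b, nmax = nmax)
}

# angular functions pi_n(mu), tau_n(mu) for n = 1..nmax
mie_pitau <- function(mu, nmax) {
  pi_n <- numeric(nmax)
  tau_n <- numeric(nmax)
  pim1 <- 0; pi_n[1] <- 1
  tau_n[1] <- mu
  if (nmax >= 2) {
    for (n in 2:nmax) {
      pi_n[n] <- (2 * n - 1) / (n - 1) * mu * pi_n[n - 1L] -
        n / (n - 1) * (if (n == 2) pim1 else pi_n[n - 2L])
      tau_n[n] <- n * mu * pi_n[n] - (n + 1) * pi_n[n - 1L]
    }
  }
  list(pi_n = pi_n, tau_n = tau_n)
}

#' Mie scattering amplitudes S1, S2
#'
#' Computes the complex amplitude functions of a homogeneous sphere at the
#' requested scattering angles, with the partial-wave series truncated at
#' the Wiscombe criterion \code{x + 4 x^(1/3) + 2}.
#'
#' @param inp \code{mie_input} object (or size parameter, with \code{m} given)
#' @param theta scattering angles in degrees, in \code{[0, 180]}
#' @param m relative refractive index (used when \code{inp} is numeric)
#' @return data.frame with columns \code{theta}, \code{S1}, \code{S2}
#'   (complex)
#' @export
mie_amplitudes <- function(inp, theta, m = NULL) {
  if (is.numeric(inp) && !is.null(m)) inp <- mie_input(inp, m)
  stopifnot(inherits(inp, "mie_input"), all(theta >= 0), all(theta <= 180))
  ab <- mie_ab(inp$x, inp$m)
  n <- seq_len(ab$nmax)
  w <- (2 * n + 1) / (n * (n + 1))
  S1 <- S2 <- complex(length(theta))
  for (i in seq_along(theta)) {
    mu <- cos(theta[i] * pi / 180)
    pt <- mie_pitau(mu, ab$nmax)
    S1[i] <- sum(w * (ab$a * pt$pi_n + ab$b * pt$tau_n))
    S2[i] <- sum(w * (ab$a * pt$tau_n + ab$b * pt$pi_n))
  }
  data.frame(theta = theta, S1 = S1, S2 = S2)
}

#' Mie Mueller matrix curve
#'
#' @param inp \code{mie_input}
#' @param angles scattering angles in degrees
#' @param normalize \code{"raw"} for unnormalized matrices, \code{"M11"} to
#'   divide every element by M11 at the same angle
#' @return object of class \code{mm_curve}: list with \code{angles},
#'   \code{mm} (list of 4x4 matrices) and the normalization tag
#' @export
mie_mueller <- function(inp, angles = seq(0, 180, by = 1),
                        normalize = c("raw", "M11")) {
  normalize <- match.arg(normalize)
  amp <- mie_amplitudes(inp, angles)
  mm <- lapply(seq_along(angles), function(i) {
    S <- diag(c(amp$S2[i], amp$S1[i]))
    M <- mueller_from_amplitudes(S)
    if (normalize == "M11") M / M[1, 1] else M
  })
  structure(list(angles = angles, mm = mm, normalization = normalize),
            class = "mm_curve")
}
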