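# Independent oracles used across tests.

# Mie coefficients via base-R half-integer Bessel functions (real index
# only) -- an implementation route independent of the package's
# recurrence-based series.
oracle_mie_S12 <- function(x, m, theta_deg) {
  stopifnot(Im(m) == 0)
  m <- Re(m)
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  n <- seq_len(nmax)
  sph_j <- function(nu, z) sqrt(pi / (2 * z)) * besselJ(z, nu + 0.5)
  sph_y <- function(nu, z) sqrt(pi / (2 * z)) * besselY(z, nu + 0.5)
  psi <- function(nu, z) z * sph_j(nu, z)
  chi <- function(nu, z) -z * sph_y(nu, z)
  xi <- function(nu, z) psi(nu, z) - 1i * chi(nu, z)
  dpsi <- psi(n - 1, x) - n / x * psi(n, x)
  dxi <- xi(n - 1, x) - n / x * xi(n, x)
  psm <- psi(n, m * x)
  dpsm <- psi(n - 1, m * x) - n / (m * x) * psi(n, m * x)
  a <- (m * psm * dpsi - psi(n, x) * dpsm) /
    (m * psm * dxi - xi(n, x) * dpsm)
  b <- (psm * dpsi - m * psi(n, x) * dpsm) /
    (psm * dxi - m * xi(n, x) * dpsm)
  mu <- cos(theta_deg * pi / 180)
  pi_n <- numeric(nmax); tau_n <- numeric(nmax)
  pi_n[1] <- 1; tau_n[1] <- mu
  for (k in 2:nmax) {
    pm2 <- if (k >= 3) pi_n[k - 2] else 0
    pi_n[k] <- (2 * k - 1) / (k - 1) * mu * pi_n[k - 1] - k / (k - 1) * pm2
    tau_n[k] <- k * mu * pi_n[k] - (k + 1) * pi_n[k - 1]
  }
  w <- (2 * n + 1) / (n * (n + 1))
  list(S1 = sum(w * (a * pi_n + b * tau_n)),
       S2 = sum(w * (a * tau_n + b * pi_n)))
}

# free-space dyadic Green tensor written out independently from the
# radiating-dipole field (oracle for the solver's interaction kernel)
oracle_green <- function(rvec, k) {
  r <- sqrt(sum(rvec^2))
  u <- rvec / r
  e <- exp(1i * k * r)
  (e * k^2 / r) * (diag(3) - outer(u, u)) +
    e * (1 / r^3 - 1i * k / r^2) * (3 * outer(u, u) - diag(3))
}

# Stokes vector of a complex (parallel, perpendicular) field pair,
# Bohren & Huffman convention: V = i (E1 E2* - E2 E1*)
oracle_stokes <- function(E) {
  c(Mod(E[1])^2 + Mod(E[2])^2,
    Mod(E[1])^2 - Mod(E[2])^2,
    2 * Re(E[1] * Conj(E[2])),
    2 * Im(Conj(E[1]) * E[2]))
}

# small two-dipole grid constructed by hand (positions on a lattice)
two_dipole_grid <- function(d_s, k_sep = 1L) {
  structure(list(
    positions = rbind(c(0, 0, 0), c(k_sep * d_s, 0, 0)),
    spacing = d_s, n_dipoles = 2L,
    dims = c(k_sep + 1L, 1L, 1L)), class = "dipole_grid")
}
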