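# Discrete dipole approximation on a cubic lattice with FFT-accelerated
# block-Toeplitz matrix-vector products and a BiCGSTAB Krylov solver.
#
# The scatterer is a set of point dipoles at lattice sites (a dipole_grid).
# Coupled-dipole system:  P_j / alpha - sum_{k != j} G_jk P_k = E_inc(r_j),
# where G is the free-space dyadic Green tensor (time factor exp(-i omega t),
# outgoing waves exp(+ikr)).  Lengths in micrometres throughout.

#' Optical parameters for scattering simulations
#'
#' Defaults reproduce the red-blood-cell conditions used throughout the
#' package: cells in saline/PBS (medium index 1.33), 0.472 um vacuum
#' wavelength, relative refractive index 1.053 + 1e-4i.
#'
#' @param wavelength vacuum wavelength (um)
#' @param n_medium real refractive index of the host medium (>= 1)
#' @param m_rel complex refractive index of the scatterer relative to the
#'   medium
#' @return object of class \code{optical_params}; element \code{k} is the
#'   wavenumber in the medium (1/um)
#' @export
optical_params <- function(wavelength = 0.472, n_medium = 1.33,
                           m_rel = complex(real = 1.053, imaginary = 1e-4)) {
  stopifnot(wavelength > 0, n_medium >= 1)
  structure(list(wavelength = wavelength, n_medium = n_medium,
                 m_rel = as.complex(m_rel),
                 k = 2 * pi * n_medium / wavelength),
            class = "optical_params")
}

#' Dipole spacing from the |m k d_s| criterion
#'
#' @param m complex relative refractive index
#' @param k wavenumber in the medium (1/um)
#' @param target target value of |m k d_s| (default 0.45)
#' @return spacing d_s in um
#' @export
default_spacing <- function(m, k, target = 0.45) {
  stopifnot(Mod(m) > 0, k > 0)
  target / (Mod(m) * k)
}

#' Dipole polarizability
#'
#' Clausius-Mossotti polarizability with one of three corrections:
#' \code{"fcd"} (default) the filtered-coupled-dipole self term, consistent
#' with the filtered Green tensor used by the solver and the most accurate
#' at the working lattice density; \code{"ldr"} the lattice dispersion
#' relation of Draine & Goodman (with radiative reaction); \code{"cm"} the
#' plain static form.  Vectorized over \code{m_rel} (boundary voxels of a
#' weighted grid carry per-dipole effective indices).
#'
#' @param m_rel complex relative refractive index (scalar or vector)
#' @param d_s lattice spacing (um)
#' @param k wavenumber in the medium (1/um)
#' @param prescription \code{"fcd"}, \code{"ldr"} or \code{"cm"}
#' @param S polarization/propagation geometry factor of the LDR correction,
#'   \code{sum_j (a_j e_j)^2}; 0 for propagation along a lattice axis with
#'   polarization along another axis
#' @return complex polarizability (um^3), same length as \code{m_rel}
#' @export
polarizability <- function(m_rel, d_s, k, prescription = c("fcd", "ldr", "cm"),
                           S = 0) {
  prescription <- match.arg(prescription)
  m2 <- m_rel^2
  a_cm <- 3 * d_s^3 / (4 * pi) * (m2 - 1) / (m2 + 2)
  if (prescription == "cm") return(a_cm)
  kd <- k * d_s
  if (prescription == "ldr") {
    b1 <- -1.891531; b2 <- 0.1648469; b3 <- -1.7700004
    return(a_cm / (1 + (a_cm / d_s^3) *
                     ((b1 + m2 * b2 + m2 * b3 * S) * kd^2 -
                        2 / 3 * 1i * kd^3)))
  }
  # fcd: 1/alpha = 1/(chi d^3) - G_F(0); the filtered self term G_F(0)
  # already carries the local-field (Lorentz) exclusion, so it combines
  # with the bare susceptibility chi = (m^2-1)/(4 pi), not with alpha_CM
  kF <- pi / d_s
  D <- 2 / (3 * pi) * (2 * k^2 * kF - kF^3 / 3 +
                         k^3 * log((kF - k) / (kF + k))) +
    2 / 3 * 1i * k^3
  out <- 1 / (4 * pi / ((m2 - 1) * d_s^3) - D)
  out[m2 == 1] <- 0
  out
}

#' Incident plane wave
#'
#' @param direction unit propagation vector
#' @param polarization complex polarization vector, transverse to
#'   \code{direction}
#' @return object of class \code{incident_wave}
#' @export
incident_wave <- function(direction = c(0, 0, 1), polarization = c(1, 0, 0)) {
  direction <- as.numeric(direction)
  polarization <- as.complex(polarization)
  stopifnot(length(direction) == 3, length(polarization) == 3)
  direction <- direction / sqrt(sum(direction^2))
  nrm <- sqrt(sum(Mod(polarization)^2))
  stopifnot(nrm > 0)
  polarization <- polarization / nrm
  if (Mod(sum(direction * polarization)) > 1e-10)
    stop("polarization must be transverse to the propagation direction")
  structure(list(direction = direction, polarization = polarization),
            class = "incident_wave")
}

# ---- Green tensor kernel --------------------------------------------------

# Dyadic Green tensor components for displacement (dx, dy, dz) arrays.
# For a radial scalar phi(R): G_ab = dA delta_ab + dB rhat_a rhat_b with
# dA = k^2 phi + phi'/R and dB = phi'' - phi'/R.
#   coupling "point": phi = exp(ikR)/R (free-space point dipoles)
#   coupling "fcd":   phi = the low-pass-filtered Green function with
#                     spectral cutoff kF = pi/d_s (filtered coupled
#                     dipoles), expressed through Si/Ci integrals
green_components <- function(dx, dy, dz, k, coupling = "point", kF = NULL) {
  r2 <- dx * dx + dy * dy + dz * dz
  r <- sqrt(r2)
  zero <- r == 0
  r[zero] <- 1  # avoid 0/0; zeroed below
  if (coupling == "point") {
    e <- exp(1i * k * r) / r
    C1 <- k^2 * e
    C2 <- e * (1 / r2 - 1i * k / r)
    dA <- C1 - C2
    dB <- 3 * C2 - C1
  } else {
    stopifnot(!is.null(kF), kF > k)
    dims <- dim(r)
    rv <- as.vector(r)
    sa <- sici((kF - k) * rv)
    sb <- sici((kF + k) * rv)
    skr <- sin(k * rv); ckr <- cos(k * rv)
    sF <- sin(kF * rv); cF <- cos(kF * rv)
    Nn <- ckr * (sa$si + sb$si) + skr * (sa$ci - sb$ci)
    Mm <- ckr * (sa$ci - sb$ci) - skr * (sa$si + sb$si)
    phi <- Nn / (pi * rv) + 1i * skr / rv
    dphi <- (rv * k * Mm - Nn + 2 * sF) / (pi * rv^2) +
      1i * (k * ckr / rv - skr / rv^2)
    d2phi <- (-rv^2 * k^2 * Nn - 2 * rv * k * Mm + 2 * Nn +
                2 * rv * kF * cF - 6 * sF) / (pi * rv^3) +
      1i * (-k^2 * skr / rv - 2 * k * ckr / rv^2 + 2 * skr / rv^3)
    dA <- k^2 * phi + dphi / rv
    dB <- d2phi - dphi / rv
    if (!is.null(dims)) { dim(dA) <- dims; dim(dB) <- dims }
  }
  ux <- dx / r; uy <- dy / r; uz <- dz / r
  out <- list(
    xx = dA + dB * ux * ux, xy = dB * ux * uy, xz = dB * ux * uz,
    yy = dA + dB * uy * uy, yz = dB * uy * uz, zz = dA + dB * uz * uz)
  lapply(out, function(g) { g[zero] <- 0; g })
}

# environment caching the most recent FFT'd kernel (keyed on dims, d_s, k);
# orientations of one shape share a bounding cube, so this almost always hits
.dda_cache <- new.env(parent = emptyenv())

dda_kernel_fft <- function(n_dims, d_s, k, coupling = "point") {
  key <- paste(c(n_dims, signif(d_s, 12), signif(k, 12), coupling),
               collapse = "_")
  if (identical(.dda_cache$key, key)) return(.dda_cache$kern)
  pad <- vapply(n_dims, function(n) stats::nextn(2L * n - 1L, c(2, 3, 5)),
                integer(1))
  disp <- function(N, n) {
    i <- 0:(N - 1)
    d <- ifelse(i <= n - 1, i, ifelse(i >= N - n + 1, i - N, NA_real_))
    d * d_s
  }
  dxv <- disp(pad[1], n_dims[1])
  dyv <- disp(pad[2], n_dims[2])
  dzv <- disp(pad[3], n_dims[3])
  Dx <- array(dxv, dim = pad)
  Dy <- array(rep(dyv, each = pad[1]), dim = pad)
  Dz <- array(rep(dzv, each = pad[1] * pad[2]), dim = pad)
  bad <- is.na(Dx) | is.na(Dy) | is.na(Dz)
  Dx[bad] <- 0; Dy[bad] <- 0; Dz[bad] <- 0
  g <- green_components(Dx, Dy, Dz, k, coupling = coupling, kF = pi / d_s)
  g <- lapply(g, function(a) { a[bad] <- 0; stats::fft(a) })
  kern <- list(fft = g, pad = pad, n_dims = n_dims)
  .dda_cache$key <- key
  .dda_cache$kern <- kern
  kern
}

# Map grid positions to 1-based lattice indices and padded-array linear
# indices.  Positions must lie on a cubic lattice with pitch d_s.
grid_indices <- function(grid, kern) {
  pos <- grid$positions
  ii <- round(sweep(pos, 2, apply(pos, 2, min)) / grid$spacing) + 1L
  pad <- kern$pad
  as.integer((ii[, 3] - 1L) * pad[1] * pad[2] + (ii[, 2] - 1L) * pad[1] +
               ii[, 1])
}

# FFT circular-convolution product Y = G X on the occupied sites.
# x: N x 3 complex matrix of dipole moments; returns N x 3 matrix of fields.
dda_green_apply <- function(x, idx, kern) {
  pad <- kern$pad
  np <- prod(pad)
  F <- vector("list", 3)
  for (a in 1:3) {
    X <- array(0i, dim = pad)
    X[idx] <- x[, a]
    F[[a]] <- stats::fft(X)
  }
  g <- kern$fft
  Yx <- stats::fft(g$xx * F[[1]] + g$xy * F[[2]] + g$xz * F[[3]],
                   inverse = TRUE)
  Yy <- stats::fft(g$xy * F[[1]] + g$yy * F[[2]] + g$yz * F[[3]],
                   inverse = TRUE)
  Yz <- stats::fft(g$xz * F[[1]] + g$yz * F[[2]] + g$zz * F[[3]],
                   inverse = TRUE)
  cbind(Yx[idx], Yy[idx], Yz[idx]) / np
}

# Dense interaction application (oracle for small grids)
dda_green_apply_dense <- function(x, pos, k, coupling = "point",
                                  d_s = NULL) {
  n <- nrow(pos)
  out <- matrix(0i, n, 3)
  for (j in seq_len(n)) {
    d <- sweep(pos, 2, pos[j, ])
    g <- green_components(d[, 1], d[, 2], d[, 3], k, coupling = coupling,
                          kF = if (is.null(d_s)) NULL else pi / d_s)
    out[j, 1] <- sum(g$xx * x[, 1] + g$xy * x[, 2] + g$xz * x[, 3])
    out[j, 2] <- sum(g$xy * x[, 1] + g$yy * x[, 2] + g$yz * x[, 3])
    out[j, 3] <- sum(g$xz * x[, 1] + g$yz * x[, 2] + g$zz * x[, 3])
  }
  out
}

# Unpreconditioned BiCGSTAB for complex non-Hermitian systems.
bicgstab <- function(matvec, b, tol = 1e-5, maxit = 500L) {
  x <- 0 * b
  r <- b
  bn <- sqrt(sum(Mod(b)^2))
  if (bn == 0) return(list(x = x, residual = 0, iterations = 0L,
                           converged = TRUE))
  r0 <- r
  rho <- alpha <- omega <- 1 + 0i
  v <- p <- 0 * b
  for (it in seq_len(maxit)) {
    rho1 <- sum(Conj(r0) * r)
    if (Mod(rho1) < 1e-300) break
    beta <- (rho1 / rho) * (alpha / omega)
    p <- r + beta * (p - omega * v)
    v <- matvec(p)
    alpha <- rho1 / sum(Conj(r0) * v)
    s <- r - alpha * v
    if (sqrt(sum(Mod(s)^2)) / bn < tol) {
      x <- x + alpha * p
      return(list(x = x, residual = sqrt(sum(Mod(s)^2)) / bn,
                  iterations = it, converged = TRUE))
    }
    t <- matvec(s)
    omega <- sum(Conj(t) * s) / sum(Mod(t)^2)
    x <- x + alpha * p + omega * s
    r <- s - omega * t
    rho <- rho1
    res <- sqrt(sum(Mod(r)^2)) / bn
    if (res < tol)
      return(list(x = x, residual = res, iterations = it, converged = TRUE))
  }
  list(x = x, residual = sqrt(sum(Mod(r)^2)) / bn, iterations = maxit,
       converged = FALSE)
}

#' Solve the coupled-dipole system
#'
#' Solves for the dipole moments of every lattice site under a plane-wave
#' excitation, using BiCGSTAB with an FFT-based block-Toeplitz product
#' (or a dense direct solve for small grids / as an oracle).
#'
#' @param grid \code{dipole_grid}
#' @param wave \code{incident_wave}
#' @param optics \code{optical_params}
#' @param tol relative residual tolerance (default 1e-5)
#' @param method \code{"fft"} (iterative, default) or \code{"dense"}
#'   (direct solve, feasible only for small grids)
#' @param prescription polarizability prescription, see
#'   \code{\link{polarizability}}
#' @param maxit maximum BiCGSTAB iterations
#' @return object of class \code{dda_solution}: dipole moments \code{P}
#'   (n x 3 complex), \code{residual}, \code{iterations}, plus the inputs
#' @export
solve_fields <- function(grid, wave, optics, tol = 1e-5,
                         method = c("fft", "dense"),
                         prescription = c("fcd", "ldr", "cm"),
                         maxit = 1000L) {
  method <- match.arg(method)
  prescription <- match.arg(prescription)
  stopifnot(inherits(grid, "dipole_grid"), inherits(wave, "incident_wave"),
            inherits(optics, "optical_params"))
  k <- optics$k
  mkd <- Mod(optics$m_rel) * k * grid$spacing
  if (mkd > 0.5)
    stop(sprintf("|m k d_s| = %.3f exceeds 0.5: grid too coarse", mkd))
  if (mkd > 0.451)
    warning(sprintf("|m k d_s| = %.3f above the 0.45 accuracy criterion", mkd))
  alpha <- grid_polarizability(grid, optics, prescription)
  coupling <- if (prescription == "fcd") "fcd" else "point"
  pos <- grid$positions
  Einc <- outer(exp(1i * k * drop(pos %*% wave$direction)),
                wave$polarization)
  if (method == "dense") {
    A <- dda_dense_matrix(grid, optics, alpha, coupling = coupling)
    Pv <- solve(A, as.vector(t(Einc)))
    P <- matrix(Pv, ncol = 3, byrow = TRUE)
    sol <- list(P = P, residual = 0, iterations = 0L, converged = TRUE)
  } else {
    kern <- dda_kernel_fft(grid$dims, grid$spacing, k, coupling = coupling)
    idx <- grid_indices(grid, kern)
    mv <- function(v) {
      x <- matrix(v, ncol = 3)
      as.vector(x - alpha_apply(alpha, dda_green_apply(x, idx, kern)))
    }
    res <- bicgstab(mv, as.vector(alpha_apply(alpha, Einc)), tol = tol,
                    maxit = maxit)
    if (!res$converged)
      stop(sprintf("DDA solver did not converge: residual %.2e after %d iterations",
                   res$residual, res$iterations))
    sol <- list(P = matrix(res$x, ncol = 3), residual = res$residual,
                iterations = res$iterations, converged = TRUE)
  }
  structure(c(sol, list(grid = grid, wave = wave, optics = optics,
                        alpha = alpha, prescription = prescription)),
            class = "dda_solution")
}

# Per-dipole polarizability of a grid.  Interior voxels carry the scalar
# polarizability of the cell material.  Boundary voxels of a weighted grid
# get an anisotropic (tensor) polarizability from interface-aware
# permittivity mixing: arithmetic mixing tangential to the local surface,
# harmonic mixing along its normal.  Returned as six component vectors
# (xx, yy, zz, xy, xz, yz) of the symmetric 3x3 per-dipole tensor.
grid_polarizability <- function(grid, optics, prescription) {
  d_s <- grid$spacing
  k <- optics$k
  n <- grid$n_dipoles
  eps_c <- optics$m_rel^2
  if (is.null(grid$weights)) {
    a <- rep(polarizability(optics$m_rel, d_s, k, prescription), n)
    return(list(xx = a, yy = a, zz = a,
                xy = rep(0i, n), xz = rep(0i, n), yz = rep(0i, n),
                scalar = TRUE))
  }
  f <- grid$weights
  eps_t <- f * eps_c + (1 - f)          # tangential: arithmetic
  eps_n <- 1 / (f / eps_c + (1 - f))    # normal: harmonic
  a_t <- polarizability(sqrt(eps_t), d_s, k, prescription)
  a_n <- polarizability(sqrt(eps_n), d_s, k, prescription)
  nr <- grid$normals
  dd <- a_n - a_t                        # zero for interior voxels (nr = 0)
  list(xx = a_t + dd * nr[, 1]^2, yy = a_t + dd * nr[, 2]^2,
       zz = a_t + dd * nr[, 3]^2,
       xy = dd * nr[, 1] * nr[, 2], xz = dd * nr[, 1] * nr[, 3],
       yz = dd * nr[, 2] * nr[, 3], scalar = FALSE)
}

# y = alpha x rowwise for the per-dipole symmetric tensors
alpha_apply <- function(a, x) {
  cbind(a$xx * x[, 1] + a$xy * x[, 2] + a$xz * x[, 3],
        a$xy * x[, 1] + a$yy * x[, 2] + a$yz * x[, 3],
        a$xz * x[, 1] + a$yz * x[, 2] + a$zz * x[, 3])
}

# Dense system matrix (3N x 3N), oracle / small-problem path; diagonal
# blocks are the inverse per-dipole polarizability tensors
dda_dense_matrix <- function(grid, optics, alpha, coupling = "point") {
  pos <- grid$positions
  n <- nrow(pos)
  A <- matrix(0i, 3 * n, 3 * n)
  k <- optics$k
  kF <- if (coupling == "fcd") pi / grid$spacing else NULL
  for (j in seq_len(n)) {
    d <- -sweep(pos, 2, pos[j, ], "-")  # r_j - r_k (G is even in r)
    g <- green_components(d[, 1], d[, 2], d[, 3], k, coupling = coupling,
                          kF = kF)
    rows <- (3 * (j - 1) + 1):(3 * j)
    for (kk in seq_len(n)) {
      cols <- (3 * (kk - 1) + 1):(3 * kk)
      A[rows, cols] <- -matrix(c(g$xx[kk], g$xy[kk], g$xz[kk],
                                 g$xy[kk], g$yy[kk], g$yz[kk],
                                 g$xz[kk], g$yz[kk], g$zz[kk]), 3, 3)
    }
    aj <- matrix(c(alpha$xx[j], alpha$xy[j], alpha$xz[j],
                   alpha$xy[j], alpha$yy[j], alpha$yz[j],
                   alpha$xz[j], alpha$yz[j], alpha$zz[j]), 3, 3)
    A[rows, rows] <- solve(aj)
  }
  A
}

# ---- far field ------------------------------------------------------------

# Radiation vector V(nhat) = (I - nn) sum_j P_j exp(-i k nhat . r_j)
far_field_vector <- function(sol, nhat) {
  k <- sol$optics$k
  ph <- exp(-1i * k * drop(sol$grid$positions %*% nhat))
  v <- drop(t(sol$P) %*% ph)
  v - nhat * sum(nhat * v)
}

#' Far-field amplitude scattering matrix
#'
#' Builds the 2x2 complex amplitude matrix in the scattering-plane basis
#' from two coupled-dipole solutions for orthogonal incident polarizations.
#' Convention: \code{E_sca = exp(ikr)/(-ikr) S E_inc} with basis order
#' (parallel, perpendicular), so \code{S[1,1] = S2}, \code{S[2,2] = S1}.
#'
#' @param sol_par solution for incident polarization along the in-plane
#'   (parallel) unit vector
#' @param sol_perp solution for incident polarization along the
#'   perpendicular unit vector
#' @param scatter_direction unit scattering direction
#' @return 2x2 complex matrix
#' @export
amplitude_matrix <- function(sol_par, sol_perp, scatter_direction) {
  a <- sol_par$wave$direction
  nhat <- scatter_direction / sqrt(sum(scatter_direction^2))
  cr <- c(a[2] * nhat[3] - a[3] * nhat[2],
          a[3] * nhat[1] - a[1] * nhat[3],
          a[1] * nhat[2] - a[2] * nhat[1])
  if (sqrt(sum(cr^2)) < 1e-12) {
    # forward/backward: scattering plane degenerate; use incident pol plane
    e_perp <- Re(sol_perp$wave$polarization)
  } else e_perp <- cr / sqrt(sum(cr^2))
  e_par_s <- c(e_perp[2] * nhat[3] - e_perp[3] * nhat[2],
               e_perp[3] * nhat[1] - e_perp[1] * nhat[3],
               e_perp[1] * nhat[2] - e_perp[2] * nhat[1])
  k <- sol_par$optics$k
  v1 <- far_field_vector(sol_par, nhat)
  v2 <- far_field_vector(sol_perp, nhat)
  f <- -1i * k^3
  matrix(c(f * sum(e_par_s * v1), f * sum(e_perp * v1),
           f * sum(e_par_s * v2), f * sum(e_perp * v2)), 2, 2)
}

#' Mueller matrix from a 2x2 amplitude matrix
#'
#' Standard bilinear (coherency) map: with Stokes components defined in the
#' (parallel, perpendicular) field basis, \code{M = A (S kron S*) A^{-1}}.
#'
#' @param S 2x2 complex amplitude matrix
#' @return 4x4 real Mueller matrix (raw, unnormalized)
#' @export
mueller_from_amplitudes <- function(S) {
  stopifnot(is.matrix(S), all(dim(S) == 2))
  A <- matrix(c(1, 0, 0, 1,
                1, 0, 0, -1,
                0, 1, 1, 0,
                0, 1i, -1i, 0), 4, 4, byrow = TRUE)
  M <- A %*% (S %x% Conj(S)) %*% solve(A)
  Re(M)
}
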