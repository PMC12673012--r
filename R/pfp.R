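# Polarization feature parameters (PFPs): six scalar combinations of
# M11-normalized Mueller elements at the 60/120-degree detection angles,
# each tied to a physical property of the cell:
#   K1, K2        shape (both vanish identically for a homogeneous sphere)
#   LE60          composite size/shape linear-diattenuation index
#   LE120         surface (spiculation) index
#   T60           refractive-index-sensitive depolarization combination
#   T120          size-sensitive depolarization combination
# All formulas act on matrices with M11 = 1.

pfp_check_mm <- function(mm) {
  stopifnot(is.matrix(mm), all(dim(mm) == 4))
  if (abs(mm[1, 1] - 1) > 1e-6)
    stop("PFPs are defined on M11-normalized matrices (M11 = 1)")
  invisible(mm)
}

#' Shape parameter K1
#'
#' \code{(1 - M22) / (1 + M12)} at 60 degrees.  For a sphere M22 = M11, so
#' K1 = 0; it grows as the cell departs from sphericity.
#'
#' @param mm60 normalized 4x4 Mueller matrix at 60 degrees
#' @return scalar
#' @export
pfp_k1 <- function(mm60) {
  pfp_check_mm(mm60)
  den <- 1 + mm60[1, 2]
  if (abs(den) < 1e-9)
    stop("K1 undefined: 1 + M12 vanishes at 60 degrees")
  (1 - mm60[2, 2]) / den
}

#' Shape parameter K2
#'
#' \code{M14 / (1 + M14)} at 60 degrees; zero for a sphere (M14 = 0).
#'
#' @param mm60 normalized 4x4 Mueller matrix at 60 degrees
#' @return scalar
#' @export
pfp_k2 <- function(mm60) {
  pfp_check_mm(mm60)
  den <- 1 + mm60[1, 4]
  if (abs(den) < 1e-9)
    stop("K2 undefined: 1 + M14 vanishes at 60 degrees")
  mm60[1, 4] / den
}

#' Linear orthogonal polarization attenuation differential index LE
#'
#' \code{(M12 + M21) / 2} at the stated angle.
#'
#' @param mm normalized 4x4 Mueller matrix
#' @param which 60 or 120 (informational tag; the formula is identical)
#' @return scalar
#' @export
pfp_le <- function(mm, which = c(60, 120)) {
  pfp_check_mm(mm)
  (mm[1, 2] + mm[2, 1]) / 2
}

#' Depolarization parameter T at 60 degrees
#'
#' \code{(M33 + M44) / 2}; tracks the cell refractive index.
#'
#' @param mm60 normalized 4x4 Mueller matrix at 60 degrees
#' @return scalar
#' @export
pfp_t60 <- function(mm60) {
  pfp_check_mm(mm60)
  (mm60[3, 3] + mm60[4, 4]) / 2
}

#' Depolarization parameter T at 120 degrees
#'
#' \code{(-M22 + M33 + M44) / 3}; tracks the cell size.
#'
#' @param mm120 normalized 4x4 Mueller matrix at 120 degrees
#' @return scalar
#' @export
pfp_t120 <- function(mm120) {
  pfp_check_mm(mm120)
  (-mm120[2, 2] + mm120[3, 3] + mm120[4, 4]) / 3
}

#' Full PFP vector from a Mueller-matrix pair
#'
#' @param pair \code{mm_pair} (normalized matrices at 60 and 120 degrees)
#' @return named numeric vector (K1, K2, LE60, LE120, T60, T120)
#' @export
pfp_vector <- function(pair) {
  stopifnot(inherits(pair, "mm_pair"))
  m60 <- pair$mm[["60"]]; m120 <- pair$mm[["120"]]
  if (is.null(m60) || is.null(m120))
    stop("pfp_vector requires matrices at both 60 and 120 degrees")
  c(K1 = pfp_k1(m60), K2 = pfp_k2(m60),
    LE60 = pfp_le(m60, 60), LE120 = pfp_le(m120, 120),
    T60 = pfp_t60(m60), T120 = pfp_t120(m120))
}
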