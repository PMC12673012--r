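# Parametric red-blood-cell geometry: the biconcave quartic surface, the
# disc-to-sphere morph family, spiculated spheres, and cubic-lattice
# discretization into dipole grids.  Units: micrometres; z is the symmetry
# axis of the unrotated cell; the shape centroid sits at a lattice-cell
# center.

#' Biconcave disc parameters
#'
#' The four classical discocyte dimensions: diameter \code{d}, central
#' thickness \code{b}, diameter \code{c} of the maximum-thickness ring and
#' maximum thickness \code{h}.  Defaults use the shape ratios b/d = 0.18,
#' c/d = 0.62, h/d = 0.35.
#'
#' @param d cell diameter (um)
#' @param b central (dimple) thickness (um); default 0.18 d
#' @param c diameter of the thickest ring (um); default 0.62 d
#' @param h maximum thickness (um); default 0.35 d
#' @return object of class \code{biconcave_params}
#' @export
biconcave_params <- function(d, b = 0.18 * d, c = 0.62 * d, h = 0.35 * d) {
  stopifnot(d > 0, b > 0, c > 0, h > 0)
  if (!(b < h)) stop("degenerate biconcave parameters: need b < h (b = h has no thickness extremum)")
  if (!(h < d)) stop("invalid biconcave parameters: need h < d")
  if (!(c < d)) stop("invalid biconcave parameters: need c < d")
  structure(list(d = d, b = b, c = c, h = h), class = "biconcave_params")
}

#' Solve the implicit-surface coefficients of the biconcave disc
#'
#' The surface is the quartic
#' \deqn{f(r, z) = r^4 + 2 S r^2 z^2 + z^4 + P r^2 + Q z^2 + R = 0,}
#' with \eqn{r^2 = x^2 + y^2}.  The four coefficients are fixed by four
#' constraints: the surface passes through (d/2, 0) (equator) and (0, b/2)
#' (dimple), passes through (c/2, h/2), and has its thickness extremum
#' there (radial derivative of f vanishes).  All four constraints are
#' linear in (S, P, Q, R), so the system is solved exactly.
#'
#' @param p \code{biconcave_params}
#' @return object of class \code{implicit_coeffs} with elements S, P, Q, R
#' @export
solve_biconcave_coeffs <- function(p) {
  stopifnot(inherits(p, "biconcave_params"))
  rd <- p$d / 2; rb <- p$b / 2; rc <- p$c / 2; rh <- p$h / 2
  A <- rbind(
    c(0,                rd^2, 0,    1),   # f(d/2, 0)  = 0
    c(0,                0,    rb^2, 1),   # f(0, b/2)  = 0
    c(2 * rc^2 * rh^2,  rc^2, rh^2, 1),   # f(c/2, h/2) = 0
    c(2 * rh^2,         1,    0,    0))   # df/dr = 0 at (c/2, h/2)
  rhs <- c(-rd^4, -rb^4, -(rc^4 + rh^4), -2 * rc^2)
  sol <- tryCatch(solve(A, rhs), error = function(e)
    stop("no solution for biconcave coefficients (singular constraint system): ",
         conditionMessage(e)))
  co <- structure(list(S = sol[1], P = sol[2], Q = sol[3], R = sol[4]),
                  class = "implicit_coeffs")
  resid <- biconcave_residuals(co, p)
  if (max(abs(resid)) > 1e-8)
    stop(sprintf("biconcave constraint '%s' violated (residual %.2e)",
                 names(resid)[which.max(abs(resid))], max(abs(resid))))
  co
}

# implicit function f(r, z)
implicit_f <- function(co, r, z) {
  r2 <- r^2; z2 <- z^2
  r2^2 + 2 * co$S * r2 * z2 + z2^2 + co$P * r2 + co$Q * z2 + co$R
}

#' @rdname solve_biconcave_coeffs
#' @param co \code{implicit_coeffs}
#' @return \code{biconcave_residuals}: named residuals of the four
#'   constraints (all below 1e-8 for a valid solution)
#' @export
biconcave_residuals <- function(co, p) {
  rd <- p$d / 2; rb <- p$b / 2; rc <- p$c / 2; rh <- p$h / 2
  c(equator  = implicit_f(co, rd, 0),
    dimple   = implicit_f(co, 0, rb),
    ring     = implicit_f(co, rc, rh),
    extremum = 4 * rc^3 + 4 * co$S * rc * rh^2 + 2 * co$P * rc)
}

#' Point-in-shape predicate for the implicit surface
#'
#' Sign convention: \code{f(r, z) <= 0} is inside (boundary included).
#'
#' @param points numeric 3-vector or n x 3 matrix of (x, y, z) in um
#' @param coeffs \code{implicit_coeffs}
#' @return logical vector
#' @export
is_inside <- function(points, coeffs) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  r <- sqrt(points[, 1]^2 + points[, 2]^2)
  implicit_f(coeffs, r, points[, 3]) <= 0
}

# upper-surface half thickness z(r) from the quartic (NA outside the rim)
biconcave_halfthick <- function(co, r) {
  bq <- 2 * co$S * r^2 + co$Q
  cq <- r^4 + co$P * r^2 + co$R
  disc <- bq^2 - 4 * cq
  z2 <- (-bq + sqrt(pmax(disc, 0))) / 2
  out <- sqrt(pmax(z2, 0))
  out[disc < 0 | z2 < 0] <- NA_real_
  out
}

# cell volume from the quartic profile by radial integration
biconcave_volume <- function(co, rmax) {
  f <- function(r) {
    z <- biconcave_halfthick(co, r)
    z[is.na(z)] <- 0
    4 * pi * r * z
  }
  stats::integrate(f, 0, rmax, rel.tol = 1e-9, subdivisions = 400L)$value
}

# ---- shape objects --------------------------------------------------------

new_shape <- function(type, inside, bound, symmetry, params = list()) {
  structure(list(type = type, inside = inside, bound = bound,
                 symmetry = symmetry, params = params), class = "rbc_shape")
}

#' Shape constructors
#'
#' \code{shape_sphere} builds a sphere, \code{shape_biconcave} the standard
#' biconcave disc.  Both return an \code{rbc_shape}: a list carrying an
#' inside/outside predicate over n x 3 point matrices, a bounding radius
#' and a symmetry tag (\code{"isotropic"}, \code{"axisymmetric"} or
#' \code{"none"}) that drives orientation-sampling defaults.
#'
#' @param d diameter (um)
#' @return \code{rbc_shape}
#' @export
shape_sphere <- function(d) {
  stopifnot(d > 0)
  r2 <- (d / 2)^2
  new_shape("sphere",
            function(p) p[, 1]^2 + p[, 2]^2 + p[, 3]^2 <= r2,
            bound = d / 2, symmetry = "isotropic", params = list(d = d))
}

#' @rdname shape_sphere
#' @param p \code{biconcave_params} (alternatively pass \code{d} alone to
#'   use the default ratios)
#' @export
shape_biconcave <- function(p) {
  if (is.numeric(p)) p <- biconcave_params(p)
  co <- solve_biconcave_coeffs(p)
  new_shape("biconcave", function(pts) is_inside(pts, co),
            bound = p$d / 2, symmetry = "axisymmetric",
            params = list(biconcave = p, coeffs = co))
}

#' Morph a biconcave disc toward a sphere
#'
#' Linearly interpolates the thickness ratios b/d and h/d toward equality
#' (their midpoint) as the morph fraction t goes from 0 to 1, which raises
#' edge curvature while filling in the central concavity; the result is
#' rescaled isotropically so the equivalent diameter (volume) of the t = 0
#' cell is conserved.  t = 1 returns a true sphere of that equivalent
#' diameter (the quartic cannot represent the sphere as an f <= 0 region).
#'
#' @param p \code{biconcave_params}
#' @param t morph fraction in [0, 1]
#' @return \code{rbc_shape}
#' @export
morph_shape <- function(p, t) {
  if (is.numeric(p)) p <- biconcave_params(p)
  stopifnot(t >= 0, t <= 1)
  co0 <- solve_biconcave_coeffs(p)
  V0 <- biconcave_volume(co0, p$d / 2)
  d_eq <- (6 * V0 / pi)^(1 / 3)
  if (t >= 1) {
    sh <- shape_sphere(d_eq)
    sh$params$morph_t <- 1
    return(sh)
  }
  if (t == 0) {
    sh <- shape_biconcave(p)
    sh$params$morph_t <- 0
    return(sh)
  }
  mid <- (p$b + p$h) / 2
  bt <- p$b + t * (mid - p$b)
  ht <- p$h + t * (mid - p$h)
  pt <- biconcave_params(p$d, b = bt, c = p$c, h = ht)
  cot <- solve_biconcave_coeffs(pt)
  Vt <- biconcave_volume(cot, p$d / 2)
  s <- (V0 / Vt)^(1 / 3)   # isotropic rescale conserving volume
  new_shape("morph",
            function(pts) is_inside(pts / s, cot),
            bound = s * p$d / 2, symmetry = "axisymmetric",
            params = list(biconcave = p, morph_t = t, coeffs = cot,
                          scale = s))
}

#' Spiculated-sphere specification
#'
#' @param base_diameter sphere diameter (um)
#' @param amplitude spicule height above the sphere surface (um); the
#'   physiological echinocyte range is base_diameter/20 to base_diameter/10
#' @param n_spicules number of conical protrusions
#' @param base_halfwidth angular half-width of each cone base (degrees)
#' @param seed RNG seed for the random spicule directions
#' @return object of class \code{spicule_spec}
#' @export
spicule_spec <- function(base_diameter, amplitude,
                         n_spicules = 20, base_halfwidth = 15, seed = 1) {
  stopifnot(base_diameter > 0, amplitude >= 0, n_spicules >= 1,
            base_halfwidth > 0)
  structure(list(base_diameter = base_diameter, amplitude = amplitude,
                 n_spicules = as.integer(n_spicules),
                 base_halfwidth = base_halfwidth, seed = seed),
            class = "spicule_spec")
}

#' Spiculated sphere (echinocyte model)
#'
#' Union of a base sphere and \code{n_spicules} cones whose apexes sit at
#' radius \code{base_diameter/2 + amplitude} along seeded random surface
#' directions.  The same seed always reproduces the same shape.
#'
#' @param spec \code{spicule_spec}
#' @return \code{rbc_shape}
#' @export
make_spiculated <- function(spec) {
  stopifnot(inherits(spec, "spicule_spec"))
  rho <- spec$base_diameter / 2
  A <- spec$amplitude
  w <- spec$base_halfwidth * pi / 180
  dirs <- with_seed(spec$seed, {
    u <- matrix(stats::rnorm(3 * spec$n_spicules), ncol = 3)
    u / sqrt(rowSums(u^2))
  })
  inside <- function(p) {
    rr <- sqrt(rowSums(p^2))
    ins <- rr <= rho
    if (A > 0) {
      cand <- which(!ins & rr <= rho + A)
      if (length(cand)) {
        pr <- p[cand, , drop = FALSE] / rr[cand]
        # angle to nearest spicule axis
        ca <- pr %*% t(dirs)
        phi <- acos(pmin(pmax(apply(ca, 1, max), -1), 1))
        ins[cand] <- phi <= w & rr[cand] <= rho + A * (1 - phi / w)
      }
    }
    ins
  }
  new_shape("spiculated", inside, bound = rho + A,
            symmetry = if (A > 0) "none" else "isotropic",
            params = list(spec = spec, directions = dirs))
}

#' Rotate a shape
#'
#' Returns the shape rotated by a body-to-lab rotation matrix; used for
#' orientation averaging with a fixed laboratory detector geometry.
#'
#' @param shape \code{rbc_shape}
#' @param Rm 3x3 rotation matrix
#' @return \code{rbc_shape}
#' @export
rotate_shape <- function(shape, Rm) {
  stopifnot(inherits(shape, "rbc_shape"))
  if (shape$symmetry == "isotropic") return(shape)
  inner <- shape$inside
  new_shape(shape$type, function(p) inner(p %*% Rm), bound = shape$bound,
            symmetry = shape$symmetry, params = shape$params)
}

# ---- discretization -------------------------------------------------------

#' Discretize a shape into a cubic dipole lattice
#'
#' Lattice-cell centers lie at integer multiples of \code{d_s} (the shape
#' centroid at a cell center); a dipole is placed wherever the center is
#' inside the shape.
#'
#' @param shape \code{rbc_shape} (or a bare predicate function over n x 3
#'   matrices, in which case \code{bound} must be given)
#' @param d_s lattice spacing (um)
#' @param bound half-extent of the sampling cube (um); defaults to the
#'   shape's bounding radius
#' @param weighted if TRUE, boundary voxels are kept with a fractional
#'   volume weight estimated by sub-sampling (weighted discretization;
#'   reduces the staircase error of the scattering solver).  Default FALSE:
#'   the classical center rule, one dipole per lattice cell whose center is
#'   inside.
#' @param nsub sub-samples per axis for boundary-voxel volume fractions
#' @return object of class \code{dipole_grid}: \code{positions} (n x 3),
#'   \code{spacing}, \code{n_dipoles}, \code{dims} (sampling-cube lattice
#'   dimensions, used by the FFT solver) and, when weighted, \code{weights}
#' @export
discretize <- function(shape, d_s, bound = NULL, weighted = FALSE,
                       nsub = 8) {
  stopifnot(d_s > 0)
  if (is.function(shape)) {
    stopifnot(!is.null(bound))
    inside <- shape
  } else {
    stopifnot(inherits(shape, "rbc_shape"))
    inside <- shape$inside
    if (is.null(bound)) bound <- shape$bound
  }
  nh <- ceiling(bound / d_s) + if (weighted) 1L else 0L
  ax <- (-nh:nh) * d_s
  n1 <- length(ax)
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  if (!weighted) {
    keep <- inside(pts)
    if (!any(keep)) stop("discretization produced an empty grid: spacing too coarse for the shape")
    return(structure(list(positions = pts[keep, , drop = FALSE],
                          spacing = d_s, n_dipoles = sum(keep),
                          dims = c(n1, n1, n1)),
                     class = "dipole_grid"))
  }
  # classify voxels by their 8 corners + center; sub-sample the mixed ones
  # for a volume fraction and an outward interface normal
  corner <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) * d_s / 2
  n_in <- as.integer(inside(pts))
  for (i in seq_len(8))
    n_in <- n_in + inside(sweep(pts, 2, corner[i, ], "+"))
  f <- as.numeric(n_in == 9L)
  nrm <- matrix(0, length(f), 3)
  mixed <- which(n_in > 0L & n_in < 9L)
  if (length(mixed)) {
    off <- (seq_len(nsub) - (nsub + 1) / 2) / nsub * d_s
    sub <- as.matrix(expand.grid(off, off, off))
    ns <- nrow(sub)
    chunk <- max(1L, floor(2e6 / ns))
    for (s in split(mixed, ceiling(seq_along(mixed) / chunk))) {
      big <- pts[rep(s, each = ns), , drop = FALSE] +
        sub[rep(seq_len(ns), length(s)), ]
      ins <- matrix(inside(big), nrow = ns)
      f[s] <- colMeans(ins)
      # outward normal ~ -(centroid of inside sub-samples): first moment
      nr <- -t(crossprod(ins, sub))          # 3 x length(s)
      ln <- sqrt(colSums(nr^2))
      ok <- ln > 0
      nrm[s[ok], ] <- t(nr[, ok, drop = FALSE]) / ln[ok]
    }
  }
  keep <- f > 0
  if (!any(keep)) stop("discretization produced an empty grid: spacing too coarse for the shape")
  structure(list(positions = pts[keep, , drop = FALSE], spacing = d_s,
                 n_dipoles = sum(keep), dims = c(n1, n1, n1),
                 weights = f[keep], normals = nrm[keep, , drop = FALSE]),
            class = "dipole_grid")
}

#' Equivalent (volume-sphere) diameter of a dipole grid
#'
#' Diameter of the sphere whose volume equals the voxelized cell volume,
#' \code{(6 n d_s^3 / pi)^(1/3)}.
#'
#' @param grid \code{dipole_grid}
#' @return diameter in um
#' @export
equivalent_diameter <- function(grid) {
  stopifnot(inherits(grid, "dipole_grid"), grid$n_dipoles > 0)
  v <- if (is.null(grid$weights)) grid$n_dipoles else sum(grid$weights)
  (6 * v * grid$spacing^3 / pi)^(1 / 3)
}

#' Build a shape from a configuration list
#'
#' Accepts the JSON/YAML shape schema:
#' \code{type} one of \code{"sphere"}, \code{"biconcave"}, \code{"morph"},
#' \code{"spiculated"}; \code{d}; optional \code{ratios} (b/d, c/d, h/d);
#' \code{t} for morph; \code{spicule} sublist for spiculated shapes.
#'
#' @param cfg named list
#' @return \code{rbc_shape}
#' @export
shape_from_config <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$type))
  ratios <- cfg$ratios %||% c(b = 0.18, c = 0.62, h = 0.35)
  bp <- function() biconcave_params(cfg$d, b = ratios[[1]] * cfg$d,
                                    c = ratios[[2]] * cfg$d,
                                    h = ratios[[3]] * cfg$d)
  switch(cfg$type,
    sphere = shape_sphere(cfg$d),
    biconcave = shape_biconcave(bp()),
    morph = morph_shape(bp(), cfg$t %||% 0),
    spiculated = {
      sp <- cfg$spicule %||% list()
      make_spiculated(spicule_spec(
        base_diameter = cfg$d,
        amplitude = sp$amplitude %||% (cfg$d / 10),
        n_spicules = sp$n_spicules %||% 20,
        base_halfwidth = sp$base_halfwidth %||% 15,
        seed = sp$seed %||% cfg$seed %||% 1))
    },
    stop("unknown shape type: ", cfg$type))
}
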