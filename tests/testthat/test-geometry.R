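test_that("sphere-limit coefficients reproduce the perfect-square quartic", {
  rho <- 1.7
  co <- structure(list(S = 1, P = -2 * rho^2, Q = -2 * rho^2, R = rho^4),
                  class = "implicit_coeffs")
  set.seed(1)
  r <- runif(50, 0, 3); z <- runif(50, -3, 3)
  expect_equal(rbcpol:::implicit_f(co, r, z), (r^2 + z^2 - rho^2)^2,
               tolerance = 1e-12)
})

test_that("biconcave coefficients satisfy all four constraints", {
  p <- biconcave_params(7)   # b = 1.26, c = 4.34, h = 2.45
  expect_equal(p$b, 1.26); expect_equal(p$c, 4.34); expect_equal(p$h, 2.45)
  co <- solve_biconcave_coeffs(p)
  expect_lt(abs(rbcpol:::implicit_f(co, 3.5, 0)), 1e-8)
  expect_lt(abs(rbcpol:::implicit_f(co, 0, 0.63)), 1e-8)
  expect_lt(abs(rbcpol:::implicit_f(co, 2.17, 1.225)), 1e-8)
  expect_lt(max(abs(biconcave_residuals(co, p))), 1e-8)
})

test_that("constraint residuals stay below 1e-8 across the ratio range", {
  for (bd in c(0.1, 0.2, 0.3)) for (cd in c(0.5, 0.62, 0.75))
    for (hd in c(0.25, 0.35, 0.45)) {
      if (bd >= hd) next
      p <- biconcave_params(6.5, b = bd * 6.5, c = cd * 6.5, h = hd * 6.5)
      co <- solve_biconcave_coeffs(p)
      expect_lt(max(abs(biconcave_residuals(co, p))), 1e-8)
    }
})

test_that("degenerate b = h input is rejected with a clear failure", {
  expect_error(biconcave_params(7, b = 2.45, h = 2.45), "b < h")
})

test_that("inside predicate follows the f <= 0 sign convention", {
  p <- biconcave_params(7)
  co <- solve_biconcave_coeffs(p)
  expect_false(is_inside(c(7, 0, 0), co))        # beyond the rim
  expect_true(is_inside(c(p$c / 2, 0, 0), co))   # mid-plane of the ring
  # origin is inside iff R <= 0  (f(0,0,0) = R)
  expect_identical(unname(is_inside(c(0, 0, 0), co)), co$R <= 0)
  expect_true(co$R <= 0)  # the cell center lies inside a standard disc
})

test_that("voxelization counts match analytic volumes and lattice invariances", {
  g <- discretize(shape_sphere(0.5), 0.05)
  # center-rule count against brute-force lattice enumeration (same
  # floating-point comparison; 24 of the 30 lattice points exactly on
  # the rim are ties of the f <= 0 rule)
  ii <- as.matrix(expand.grid(i = -10:10, j = -10:10, k = -10:10)) * 0.05
  n_exact <- sum(rowSums(ii^2) <= 0.25^2)
  expect_identical(g$n_dipoles, n_exact)
  # ... which tracks the analytic sphere volume (6% discretization error
  # at 10 cells per diameter, shrinking with refinement)
  expect_equal(g$n_dipoles, pi / 6 * 10^3, tolerance = 0.07)
  # shifting the shape by one lattice pitch leaves the count unchanged
  # (diameter incommensurate with the lattice: no boundary ties)
  ds2 <- 1 / 16
  g3 <- discretize(shape_sphere(0.51), ds2)
  shifted <- function(p) shape_sphere(0.51)$inside(p - rep(ds2, 3)[col(p)])
  g4 <- discretize(shifted, ds2, bound = 0.35)
  expect_identical(g4$n_dipoles, g3$n_dipoles)
  # biconcave disc occupies less volume than its circumscribing sphere
  gb <- discretize(shape_biconcave(0.5), 0.02)
  gs <- discretize(shape_sphere(0.5), 0.02)
  expect_lt(gb$n_dipoles, gs$n_dipoles)
})

test_that("voxel count scales as the inverse cube of the spacing", {
  d <- 0.8
  for (ds in d / c(8, 16, 24, 32)) {
    g <- discretize(shape_sphere(d), ds)
    expect_equal(g$n_dipoles * ds^3, pi / 6 * d^3, tolerance = 0.05)
  }
})

test_that("dipole spacing rule gives |m k d_s| equal to the target", {
  opt <- optical_params()
  ds <- default_spacing(opt$m_rel, opt$k)
  expect_equal(Mod(opt$m_rel) * opt$k * ds, 0.45, tolerance = 1e-12)
  expect_equal(default_spacing(1 + 0i, 2), 0.45 / 2)
  expect_equal(default_spacing(opt$m_rel, 2 * opt$k), ds / 2)
})

test_that("equivalent diameter recovers sphere size and survives rotation", {
  g <- discretize(shape_sphere(1), 1 / 20)
  expect_equal(equivalent_diameter(g), 1, tolerance = 0.02)
  g1 <- structure(list(positions = matrix(0, 1, 3), spacing = 0.1,
                       n_dipoles = 1L, dims = c(1L, 1L, 1L)),
                  class = "dipole_grid")
  expect_equal(equivalent_diameter(g1), (6 * 0.1^3 / pi)^(1 / 3))
  sh <- shape_biconcave(0.9)
  ga <- discretize(sh, 0.02)
  gb <- discretize(rotate_shape(sh, euler_matrix(20, 65, 10)), 0.02)
  expect_equal(equivalent_diameter(ga), equivalent_diameter(gb),
               tolerance = (0.02^3 / ga$n_dipoles)^(1 / 3) + 0.01)
})

test_that("morph family interpolates biconcave to sphere at fixed volume", {
  p <- biconcave_params(0.9)
  m0 <- morph_shape(p, 0)
  expect_equal(m0$params$coeffs, solve_biconcave_coeffs(p))
  ds <- 0.02
  d_eq0 <- equivalent_diameter(discretize(m0, ds))
  # t = 1 voxelizes identically to the equivalent-diameter sphere
  m1 <- morph_shape(p, 1)
  expect_equal(m1$type, "sphere")
  g1 <- discretize(m1, ds)
  gs <- discretize(shape_sphere(m1$params$d), ds)
  expect_identical(g1$positions, gs$positions)
  # intermediate morphs conserve the equivalent diameter to a voxel
  for (t in c(0.3, 0.5, 0.8)) {
    gt <- discretize(morph_shape(p, t), ds)
    expect_equal(equivalent_diameter(gt), d_eq0, tolerance = 0.02)
  }
  # voxelized central thickness is non-decreasing in t
  zfine <- seq(-0.6, 0.6, by = 0.002)
  central <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(t) {
    sh <- morph_shape(p, t)
    sum(sh$inside(cbind(0, 0, zfine))) * 0.002
  }, numeric(1))
  expect_true(all(diff(central) >= -2e-3))
})

test_that("spiculated spheres are seeded, reproducible and add volume", {
  base <- spicule_spec(1, amplitude = 0, seed = 7)
  g_plain <- discretize(make_spiculated(base), 0.04)
  g_sphere <- discretize(shape_sphere(1), 0.04, bound = 0.5)
  expect_identical(g_plain$positions, g_sphere$positions)
  spec <- spicule_spec(1, amplitude = 0.1, n_spicules = 20, seed = 11)
  ga <- discretize(make_spiculated(spec), 0.04)
  gb <- discretize(make_spiculated(spec), 0.04)
  expect_identical(ga$positions, gb$positions)
  expect_gt(ga$n_dipoles, g_plain$n_dipoles)
  # different seed, different shape
  gc <- discretize(make_spiculated(spicule_spec(1, 0.1, seed = 12)), 0.04)
  expect_false(identical(ga$positions, gc$positions))
})

test_that("weighted discretization reports fractions and normals", {
  g <- discretize(shape_sphere(0.5), 0.05, weighted = TRUE)
  expect_true(all(g$weights > 0 & g$weights <= 1))
  expect_equal(sum(g$weights) * 0.05^3, pi / 6 * 0.5^3, tolerance = 0.002)
  bd <- g$weights < 1
  nn <- sqrt(rowSums(g$normals^2))
  expect_true(all(abs(nn[bd] - 1) < 1e-9))
  # boundary normals of a sphere point radially outward
  rhat <- g$positions[bd, ] / sqrt(rowSums(g$positions[bd, ]^2))
  expect_gt(min(rowSums(rhat * g$normals[bd, ])), 0.8)
})

test_that("shape configs build every family", {
  expect_equal(shape_from_config(list(type = "sphere", d = 1))$type,
               "sphere")
  expect_equal(shape_from_config(list(type = "biconcave", d = 7))$type,
               "biconcave")
  expect_equal(shape_from_config(list(type = "morph", d = 7,
                                      t = 0.4))$type, "morph")
  sp <- shape_from_config(list(type = "spiculated", d = 1,
                               spicule = list(amplitude = 0.08, seed = 2)))
  expect_equal(sp$type, "spiculated")
  expect_error(shape_from_config(list(type = "torus", d = 1)), "unknown")
})
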