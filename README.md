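# rbcpol

Polarimetric light-scattering simulation and analysis of red blood cell
(RBC) deformation.

Individual RBCs deform under osmotic, oxidative and acid–base stress —
swelling into spherocytes, flattening, or growing membrane spicules
(echinocytes) — and those shape changes are diagnostic. A dual-angle
Mueller-matrix polarimeter reads them out without labels: light scattered
by single cells is collected at 60° and 120°, and the pair of 4×4 Mueller
matrices `MM(60°), MM(120°)` fingerprints each cell's size, refractive
index, shape and surface texture. This package provides the full
computational chain for that measurement, for anyone building, validating
or interpreting single-cell polarimetric cytometry:

* **Geometry** — the biconcave disc quartic
  `r⁴ + 2Sr²z² + z⁴ + Pr² + Qz² + R = 0` (coefficients solved exactly
  from diameter `d`, dimple thickness `b`, ring diameter `c`, maximum
  thickness `h`), a volume-conserving disc→sphere morph family, seeded
  spiculated spheres, and cubic-lattice discretization.
* **Scattering** — a discrete-dipole (coupled-dipole) solver with
  FFT-accelerated block-Toeplitz products, filtered-coupled-dipole
  interaction and weighted boundary discretization, validated against an
  exact Mie series oracle; orientation averaging for free-floating cells.
* **Features** — the six polarization feature parameters
  `K1 = (1−M22^60)/(1+M12^60)`, `K2 = M14^60/(1+M14^60)`,
  `LE = (M12+M21)/2` at both angles, `T60 = (M33^60+M44^60)/2`,
  `T120 = (−M22^120+M33^120+M44^120)/3`; K1 and K2 vanish identically
  for spheres.
* **Instrument** — four-quadrant Stokes reconstruction
  `(I,Q,U,V) = (s0+s90, s0−s90, 2s45−s0−s90, s0+s90−2sL)`, Mueller
  recovery `MM = S_out·pinv(S_in)`, and microsphere calibration
  `MM_r = Mp·MM_m − Ms` fitted by least squares.
* **Mixtures** — seeded synthetic normal/spherocyte/echinocyte
  populations and a random-forest estimator of suspension composition,
  scored by the absolute error `AE = Σᵢ |Tᵢ − Pᵢ|`.

## Worked example

Simulate a 0.5 µm sphere at the RBC refractive index (1.053 + 1e-4i in
medium 1.33, wavelength 0.472 µm) and extract its features:

```r
library(rbcpol)
opt  <- optical_params()            # 0.472 um, n_med 1.33, m 1.053+1e-4i
pair <- simulate_mm(shape_sphere(0.5), opt)
round(pair$mm[["60"]], 3)
#>       [,1]  [,2]  [,3]   [,4]
#> [1,] 1.000 0.155 0.000  0.000
#> [2,] 0.155 1.000 0.000  0.000
#> [3,] 0.000 0.000 0.851 -0.502
#> [4,] 0.000 0.000 0.502  0.851
round(pfp_vector(pair), 4)
#>      K1      K2    LE60   LE120     T60    T120
#>  0.0000  0.0000  0.1551 -0.5571  0.8507 -0.6655
```

The matrix shows the sphere's exact block structure (`M22 = M11`,
`M12 = M21`, zero polarizing off-blocks), so the shape parameters K1 and
K2 are zero — the identity that separates spherocytes from discocytes.
The simulated matrix agrees with the exact Mie oracle to 0.0074
(maximum element deviation) at the default operating lattice, and to
0.006 across all angles at the finer validation lattice.

A biconcave disc, by contrast, breaks the symmetry once its orientation
is averaged (`simulate_mm(shape_biconcave(0.9), opt)` gives K1 > 0), and
spiculated cells depress LE120 — the basis for classifying stressed
cells. See `vignette("rbcpol-methods")` for the model, its assumptions,
parameter choices, and the reduced (desk) problem scale.

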