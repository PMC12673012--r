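test_that("stress presets encode the physics direction of each condition", {
  nrm <- stress_preset("normal")
  expect_equal(nrm$shape, "biconcave")
  expect_equal(nrm$morph_t, 0)
  hypo <- stress_preset("hypotonic")
  expect_gt(hypo$d_mean, nrm$d_mean * 0.72)  # swollen relative to the
  # normal cell's equivalent diameter (a 0.9 um disc has d_eq ~ 0.65 um)
  expect_lt(hypo$m_mean, nrm$m_mean)          # hemoglobin dilution
  hyper <- stress_preset("hypertonic")
  expect_lt(hyper$d_mean, nrm$d_mean)         # shrinkage
  expect_gt(hyper$m_mean, nrm$m_mean)         # hemoglobin concentration
  expect_lt(hyper$ratios[1], nrm$ratios[1])   # deeper concavity
  oxi <- stress_preset("oxidative")
  expect_equal(oxi$shape, "spiculated")
  expect_gt(mean(oxi$amp_rel_range), 0)
  expect_equal(stress_preset("alkaline")$shape, "spiculated")
  expect_equal(stress_preset("acidic")$shape, "morph")
  expect_error(stress_preset("plasma"), "unknown")
  expect_identical(stress_preset("spherocyte"), stress_preset("hypotonic"))
})

test_that("populations are reproducible and collapse without variability", {
  lib <- fixture_library()
  spec <- lib$classes$normal$spec
  a <- generate_population(spec, lib, n_cells = 25, seed = 9)
  b <- generate_population(spec, lib, n_cells = 25, seed = 9)
  expect_identical(a, b)
  expect_false(identical(
    a, generate_population(spec, lib, n_cells = 25, seed = 10)))
  frozen <- spec
  frozen$d_sd <- 0; frozen$m_sd <- 0; frozen$mm_noise_sd <- 0
  z <- generate_population(frozen, lib, n_cells = 5, seed = 1)
  feats <- z[, setdiff(names(z), "label")]
  expect_equal(max(vapply(feats, function(col) diff(range(col)),
                          numeric(1))), 0)
})

test_that("record schema converts losslessly to PFPs", {
  lib <- fixture_library()
  recs <- generate_population(lib$classes$spherocyte$spec, lib,
                              n_cells = 10, seed = 2)
  expect_equal(ncol(recs), 31)
  expect_true(all(rbcpol:::mm_element_names() %in% names(recs)))
  pf <- records_to_pfp(recs)
  expect_named(pf, c("K1", "K2", "LE60", "LE120", "T60", "T120", "label"))
  r1 <- rbcpol:::record_to_mm_pair(recs[1, ])
  expect_equal(pf$K1[1], pfp_k1(r1$mm[["60"]]))
})

test_that("mixtures draw multinomial counts and hide labels", {
  lib <- fixture_library()
  specs <- lapply(lib$classes[c("spherocyte", "echinocyte", "normal")],
                  function(e) e$spec)
  pure <- build_mixture(specs, c(1, 0, 0), 40, lib, seed = 3)
  expect_equal(unname(pure$truth), c(1, 0, 0))
  expect_true(all(pure$labels == "spherocyte"))
  expect_false("label" %in% names(pure$records))
  m1 <- build_mixture(specs, c(0.25, 0.25, 0.5), 400, lib, seed = 4)
  m2 <- build_mixture(specs, c(0.25, 0.25, 0.5), 400, lib, seed = 4)
  expect_identical(m1, m2)
  # realized fractions near nominal within 3 binomial sd
  p <- c(0.25, 0.25, 0.5)
  expect_true(all(abs(m1$truth - p) <= 3 * sqrt(p * (1 - p) / 400)))
  expect_equal(sum(m1$truth), 1)
})

test_that("classes separate as the deformation physics dictates", {
  lib <- fixture_library()
  n <- generate_population(lib$classes$normal$spec, lib, n_cells = 200,
                           seed = 21)
  s <- generate_population(lib$classes$spherocyte$spec, lib,
                           n_cells = 200, seed = 22)
  e <- generate_population(lib$classes$echinocyte$spec, lib,
                           n_cells = 200, seed = 23)
  pf_n <- records_to_pfp(n); pf_s <- records_to_pfp(s)
  pf_e <- records_to_pfp(e)
  # spherocytes sit at the K1 = 0 sphere identity; discs above it
  expect_lt(abs(mean(pf_s$K1)), 3 * sd(pf_s$K1) / sqrt(200))
  expect_gt(mean(pf_n$K1), mean(pf_s$K1))
  # spiculation depresses LE120 relative to smooth cells
  expect_lt(mean(pf_e$LE120), mean(pf_s$LE120))
  expect_lt(mean(pf_e$LE120), mean(pf_n$LE120))
  # the joint 30-element signature separates the three classes almost
  # perfectly (multivariate separation; no single PFP suffices)
  train <- rbind(n, s, e)
  rf <- train_forest(train, n_trees = 150, seed = 24)
  oob <- 1 - rf$rf$err.rate[150, "OOB"]
  expect_gte(oob, 0.95)
})

test_that("per-cell DDA backend agrees with the library at a grid node", {
  lib <- fixture_library()
  spec <- lib$classes$spherocyte$spec
  frozen <- spec
  frozen$d_sd <- 0; frozen$m_sd <- 0; frozen$mm_noise_sd <- 0
  rec <- generate_population(frozen, lib, n_cells = 1, backend = "dda",
                             seed = 5)
  node <- rbcpol:::lib_interp(lib$classes$spherocyte, spec$d_mean,
                              spec$m_mean)
  got <- as.numeric(rec[1, rbcpol:::mm_element_names()])
  expect_equal(got, unname(node$features), tolerance = 0.02)
})
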