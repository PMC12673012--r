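# Seeded synthetic cell populations at the simulator's reduced (desk)
# scale.  Each population spec encodes one stress condition as parameter
# distributions (size, refractive index, shape family, spiculation);
# per-cell Mueller-matrix pairs come either from direct reduced-scale DDA
# or from multilinear interpolation over a precomputed parameter-grid MM
# library, plus element-wise Gaussian measurement noise.  Everything is
# reproducible bit-for-bit from (spec, seed).

mm_element_names <- function(angles = c(60, 120)) {
  idx <- expand.grid(i = 1:4, j = 1:4)
  idx <- idx[!(idx$i == 1 & idx$j == 1), ]
  idx <- idx[order(idx$i, idx$j), ]
  unlist(lapply(angles, function(a) paste0("m", idx$i, idx$j, "_", a)))
}

# mm_pair -> named 30-vector of non-M11 normalized elements
mm_pair_features <- function(pair) {
  v <- c()
  for (a in c("60", "120")) {
    m <- pair$mm[[a]]
    for (i in 1:4) for (j in 1:4) if (!(i == 1 && j == 1))
      v <- c(v, m[i, j])
  }
  stats::setNames(v, mm_element_names())
}

# one record row (features) -> mm_pair with M11 = 1
record_to_mm_pair <- function(row) {
  mk <- function(angle) {
    m <- matrix(0, 4, 4); m[1, 1] <- 1
    for (i in 1:4) for (j in 1:4) if (!(i == 1 && j == 1))
      m[i, j] <- as.numeric(row[[paste0("m", i, j, "_", angle)]])
    m
  }
  mm_pair(mk(60), mk(120))
}

#' Convert 30-element records to PFP records
#'
#' @param records data.frame with the 30 normalized Mueller-element
#'   columns (plus optional \code{label})
#' @return data.frame with columns K1, K2, LE60, LE120, T60, T120 (and
#'   \code{label} when present)
#' @export
records_to_pfp <- function(records) {
  out <- t(vapply(seq_len(nrow(records)), function(i)
    pfp_vector(record_to_mm_pair(records[i, ])), numeric(6)))
  out <- as.data.frame(out)
  if ("label" %in% names(records)) out$label <- records$label
  out
}

#' Population specification
#'
#' Parameter distributions for one monodisperse synthetic population.
#' Diameter and refractive index are Gaussian (truncated at +-2.5 sd);
#' spicule amplitude is uniform over \code{amp_rel_range} times the
#' diameter.
#'
#' @param class_name one of "normal", "spherocyte", "echinocyte" (free
#'   text allowed for custom presets)
#' @param shape "biconcave", "sphere", "spiculated" or "morph"
#' @param d_mean,d_sd diameter distribution (um); disc diameter for
#'   biconcave shapes, sphere diameter otherwise
#' @param m_mean,m_sd real part of the relative refractive index
#' @param morph_t morph fraction (for shape "morph")
#' @param ratios biconcave thickness ratios (b/d, c/d, h/d)
#' @param amp_rel_range spicule amplitude range relative to diameter
#' @param n_spicules,base_halfwidth spicule geometry (see
#'   \code{\link{spicule_spec}})
#' @param mm_noise_sd additive Gaussian noise on each normalized Mueller
#'   element (measurement noise emulation)
#' @param n_cells default number of cells to generate
#' @return object of class \code{population_spec}
#' @export
population_spec <- function(class_name, shape, d_mean, d_sd, m_mean, m_sd,
                            morph_t = 0, ratios = c(0.18, 0.62, 0.35),
                            amp_rel_range = c(1 / 20, 1 / 10),
                            n_spicules = 20, base_halfwidth = 15,
                            mm_noise_sd = 0.005, n_cells = 100) {
  stopifnot(d_mean > 0, d_sd >= 0, m_sd >= 0, mm_noise_sd >= 0,
            n_cells >= 1)
  structure(list(class_name = class_name, shape = shape, d_mean = d_mean,
                 d_sd = d_sd, m_mean = m_mean, m_sd = m_sd,
                 morph_t = morph_t, ratios = ratios,
                 amp_rel_range = amp_rel_range, n_spicules = n_spicules,
                 base_halfwidth = base_halfwidth,
                 mm_noise_sd = mm_noise_sd, n_cells = n_cells),
            class = "population_spec")
}

#' Stress-condition population presets
#'
#' Desk-scale parameter presets encoding the qualitative physics of each
#' stress condition: hypotonic stress swells cells toward spheres and
#' dilutes hemoglobin (lower index); hypertonic stress shrinks them,
#' concentrates hemoglobin and deepens the concavity, with spiculation at
#' the extreme; oxidative and alkaline stress spiculate the membrane;
#' acidic stress swells cells and reduces concavity.  All sizes are at
#' the package's reduced simulation scale (~0.5-1 um), not physiological.
#'
#' @param name one of "normal", "hypotonic", "hypertonic", "oxidative",
#'   "acidic", "alkaline", or the class aliases "spherocyte" (= hypotonic
#'   endpoint) and "echinocyte" (= hypertonic/oxidative endpoint)
#' @return \code{population_spec}
#' @export
stress_preset <- function(name) {
  switch(name,
    normal = population_spec("normal", "biconcave",
                             d_mean = 0.90, d_sd = 0.045,
                             m_mean = 1.053, m_sd = 0.003),
    hypotonic = ,
    spherocyte = population_spec("spherocyte", "sphere",
                                 d_mean = 0.72, d_sd = 0.036,
                                 m_mean = 1.047, m_sd = 0.003),
    hypertonic = population_spec("hypertonic", "biconcave",
                                 d_mean = 0.80, d_sd = 0.040,
                                 m_mean = 1.059, m_sd = 0.003,
                                 ratios = c(0.14, 0.62, 0.32)),
    oxidative = ,
    echinocyte = population_spec("echinocyte", "spiculated",
                                 d_mean = 0.60, d_sd = 0.030,
                                 m_mean = 1.059, m_sd = 0.003),
    acidic = population_spec("acidic", "morph",
                             d_mean = 0.95, d_sd = 0.048,
                             m_mean = 1.049, m_sd = 0.003, morph_t = 0.5),
    alkaline = population_spec("alkaline", "spiculated",
                               d_mean = 0.58, d_sd = 0.029,
                               m_mean = 1.057, m_sd = 0.003,
                               amp_rel_range = c(1 / 20, 1 / 12)),
    stop("unknown stress preset: ", name))
}

spec_shape <- function(spec, d, amp_rel = NULL, spicule_seed = 1) {
  switch(spec$shape,
    sphere = shape_sphere(d),
    biconcave = shape_biconcave(biconcave_params(
      d, b = spec$ratios[1] * d, c = spec$ratios[2] * d,
      h = spec$ratios[3] * d)),
    morph = morph_shape(biconcave_params(
      d, b = spec$ratios[1] * d, c = spec$ratios[2] * d,
      h = spec$ratios[3] * d), spec$morph_t),
    spiculated = make_spiculated(spicule_spec(
      d, amplitude = (amp_rel %||% mean(spec$amp_rel_range)) * d,
      n_spicules = spec$n_spicules,
      base_halfwidth = spec$base_halfwidth, seed = spicule_seed)),
    stop("unknown shape: ", spec$shape))
}

#' Precompute a Mueller-matrix library over a parameter grid
#'
#' For each population spec, orientation-averaged Mueller-matrix pairs
#' are computed by reduced-scale DDA on a grid over diameter and
#' refractive index (and spicule amplitude for spiculated shapes);
#' populations are then generated by multilinear interpolation, which
#' makes 10^3-10^4-cell cohorts tractable.
#'
#' @param specs list of \code{population_spec}
#' @param n_sigma half-width of the parameter grids in population
#'   standard deviations (sampling is truncated to the same range)
#' @param n_d,n_m grid nodes for diameter and refractive index
#' @param n_orient orientations per node: named list with entries
#'   \code{axisymmetric} and \code{full} (isotropic shapes need one)
#' @param optics \code{optical_params} (the refractive-index grid
#'   overrides \code{m_rel}'s real part per node)
#' @param tol DDA solver tolerance (1e-4 suffices here: interpolation and
#'   measurement noise dominate the library's error budget)
#' @param nsub boundary sub-sampling density passed to
#'   \code{\link{discretize}}
#' @param seed RNG seed (orientation sampling, spicule directions)
#' @return object of class \code{mm_library}
#' @export
build_mm_library <- function(specs, n_sigma = 2.5, n_d = 3, n_m = 2,
                             n_orient = list(axisymmetric = 6, full = 5),
                             optics = optical_params(), tol = 1e-4,
                             nsub = 4, seed = 1) {
  lib <- list()
  angles <- c(60, 120)
  thetas <- c(0, angles)
  for (spec in specs) {
    d_grid <- if (spec$d_sd > 0)
      seq(spec$d_mean - n_sigma * spec$d_sd,
          spec$d_mean + n_sigma * spec$d_sd, length.out = n_d)
    else spec$d_mean
    m_grid <- if (spec$m_sd > 0)
      seq(spec$m_mean - n_sigma * spec$m_sd,
          spec$m_mean + n_sigma * spec$m_sd, length.out = n_m)
    else spec$m_mean
    a_grid <- if (spec$shape == "spiculated") spec$amp_rel_range else 0
    dims <- c(length(d_grid), length(m_grid), length(a_grid))
    feat <- array(NA_real_, c(dims, 30))
    m11r <- array(NA_real_, c(dims, 2))
    # one spacing and one bounding cube per class: every orientation and
    # parameter node shares the same lattice dims, so the FFT'd Green
    # kernel is built once per class
    opt_by_m <- lapply(m_grid, function(mr)
      optical_params(optics$wavelength, optics$n_medium,
                     complex(real = mr, imaginary = Im(optics$m_rel))))
    d_s <- default_spacing(max(Mod(vapply(opt_by_m, `[[`, complex(1),
                                          "m_rel"))), optics$k)
    bound_max <- max(vapply(seq_along(d_grid), function(id)
      max(vapply(seq_along(a_grid), function(ia)
        spec_shape(spec, d_grid[id],
                   amp_rel = if (spec$shape == "spiculated") a_grid[ia]
                   else NULL, spicule_seed = seed)$bound,
        numeric(1))), numeric(1)))
    for (id in seq_along(d_grid)) for (ia in seq_along(a_grid)) {
      sh <- spec_shape(spec, d_grid[id],
                       amp_rel = if (spec$shape == "spiculated")
                         a_grid[ia] else NULL, spicule_seed = seed)
      ors <- switch(sh$symmetry,
        isotropic = data.frame(alpha = 0, beta = 0, gamma = 0),
        axisymmetric = sample_axisymmetric(n_orient$axisymmetric,
                                           seed = seed),
        sample_full_n(n_orient$full, seed = seed))
      raw <- array(0, c(length(m_grid), length(thetas), 4, 4))
      for (io in seq_len(nrow(ors))) {
        o <- ors[io, ]
        grid <- discretize(rotate_shape(sh, euler_matrix(o$alpha, o$beta,
                                                         o$gamma)),
                           d_s, bound = bound_max, weighted = TRUE,
                           nsub = nsub)
        for (im in seq_along(m_grid)) {
          sx <- solve_fields(grid, incident_wave(c(0, 0, 1), c(1, 0, 0)),
                             opt_by_m[[im]], tol = tol)
          sy <- solve_fields(grid, incident_wave(c(0, 0, 1), c(0, 1, 0)),
                             opt_by_m[[im]], tol = tol)
          for (it in seq_along(thetas)) {
            a <- thetas[it] * pi / 180
            S <- amplitude_matrix(sx, sy, c(sin(a), 0, cos(a)))
            raw[im, it, , ] <- raw[im, it, , ] +
              mueller_from_amplitudes(S) / nrow(ors)
          }
        }
      }
      for (im in seq_along(m_grid)) {
        mm60 <- raw[im, 2, , ] / raw[im, 2, 1, 1]
        mm120 <- raw[im, 3, , ] / raw[im, 3, 1, 1]
        pr <- mm_pair(mm60, mm120)
        feat[id, im, ia, ] <- mm_pair_features(pr)
        m11r[id, im, ia, ] <- c(raw[im, 2, 1, 1], raw[im, 3, 1, 1]) /
          raw[im, 1, 1, 1]
      }
    }
    lib[[spec$class_name]] <- list(spec = spec, d_grid = d_grid,
                                   m_grid = m_grid, a_grid = a_grid,
                                   features = feat, m11_ratio = m11r)
  }
  structure(list(classes = lib, optics = optics, seed = seed,
                 n_orient = n_orient),
            class = "mm_library")
}

# n random full-space orientations (not a Cartesian product); used for
# library nodes where a small non-grid sample is preferable
sample_full_n <- function(n, seed = NULL) {
  with_seed(seed, data.frame(alpha = stats::runif(n, 0, 360),
                             beta = stats::runif(n, 0, 180),
                             gamma = stats::runif(n, 0, 360)))
}

# multilinear interpolation of the 30-element feature vector
lib_interp <- function(entry, d, m, a_rel = NULL) {
  wts <- function(grid, x) {
    if (length(grid) == 1) return(list(i = c(1, 1), w = c(1, 0)))
    x <- min(max(x, grid[1]), grid[length(grid)])
    i <- findInterval(x, grid, rightmost.closed = TRUE)
    i <- min(i, length(grid) - 1)
    t <- (x - grid[i]) / (grid[i + 1] - grid[i])
    list(i = c(i, i + 1), w = c(1 - t, t))
  }
  wd <- wts(entry$d_grid, d)
  wm <- wts(entry$m_grid, m)
  wa <- wts(entry$a_grid, a_rel %||% entry$a_grid[1])
  f <- numeric(30); r <- numeric(2)
  for (p in 1:2) for (q in 1:2) for (s in 1:2) {
    w <- wd$w[p] * wm$w[q] * wa$w[s]
    if (w == 0) next
    f <- f + w * entry$features[wd$i[p], wm$i[q], wa$i[s], ]
    r <- r + w * entry$m11_ratio[wd$i[p], wm$i[q], wa$i[s], ]
  }
  list(features = stats::setNames(f, mm_element_names()), m11_ratio = r)
}

# truncated-normal sampling (rejection, +-n_sigma)
rtruncnorm <- function(n, mean, sd, n_sigma = 2.5) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- abs(out - mean) > n_sigma * sd
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- abs(out - mean) > n_sigma * sd
  }
  out
}

#' Generate a monodisperse synthetic population
#'
#' Samples per-cell parameters from the spec's distributions, obtains the
#' Mueller-matrix pair (library interpolation or per-cell DDA) and adds
#' element-wise Gaussian measurement noise.
#'
#' @param spec \code{population_spec}
#' @param library \code{mm_library} (required for the default backend)
#' @param n_cells number of cells (default from the spec)
#' @param backend \code{"library"} (interpolation; fast) or \code{"dda"}
#'   (per-cell reduced-scale simulation; minutes per hundred cells)
#' @param seed RNG seed
#' @return data.frame of cell records: 30 feature columns plus
#'   \code{label}
#' @export
generate_population <- function(spec, library = NULL,
                                n_cells = spec$n_cells,
                                backend = c("library", "dda"),
                                seed = NULL) {
  backend <- match.arg(backend)
  stopifnot(inherits(spec, "population_spec"))
  with_seed(seed, {
    d <- rtruncnorm(n_cells, spec$d_mean, spec$d_sd)
    m <- rtruncnorm(n_cells, spec$m_mean, spec$m_sd)
    a_rel <- if (spec$shape == "spiculated")
      stats::runif(n_cells, spec$amp_rel_range[1], spec$amp_rel_range[2])
    else rep(0, n_cells)
    noise <- matrix(stats::rnorm(30 * n_cells, 0, spec$mm_noise_sd),
                    n_cells, 30)
    spseeds <- sample.int(1e6, n_cells)
    if (backend == "library") {
      if (is.null(library) || is.null(library$classes[[spec$class_name]]))
        stop("no library entry for class ", spec$class_name)
      entry <- library$classes[[spec$class_name]]
      feats <- t(vapply(seq_len(n_cells), function(i)
        lib_interp(entry, d[i], m[i], a_rel[i])$features, numeric(30)))
    } else {
      feats <- t(vapply(seq_len(n_cells), function(i) {
        sh <- spec_shape(spec, d[i], amp_rel = a_rel[i],
                         spicule_seed = spseeds[i])
        ors <- switch(sh$symmetry,
          isotropic = data.frame(alpha = 0, beta = 0, gamma = 0),
          axisymmetric = sample_axisymmetric(8, seed = spseeds[i]),
          sample_full_n(6, seed = spseeds[i]))
        opt <- optical_params(m_rel = complex(real = m[i],
                                              imaginary = 1e-4))
        mm_pair_features(simulate_mm(sh, opt, orientations = ors))
      }, numeric(30)))
    }
    feats <- feats + noise
    colnames(feats) <- mm_element_names()
    out <- as.data.frame(feats)
    out$label <- spec$class_name
    out
  })
}

#' Build a mixed suspension with hidden labels
#'
#' Draws per-class cell counts from a multinomial at the nominal ratios,
#' generates each class and shuffles the pooled records.  The returned
#' truth vector holds the realized (not nominal) fractions.
#'
#' @param specs named list of \code{population_spec} (one per class)
#' @param ratios nominal mixing ratios (same order/names as specs; sums
#'   to 1)
#' @param n_total total number of cells
#' @param library \code{mm_library}
#' @param seed RNG seed
#' @return list: \code{records} (features only), \code{truth} (realized
#'   fractions), \code{labels} (for diagnostics, same order as records)
#' @export
build_mixture <- function(specs, ratios, n_total, library, seed = NULL) {
  stopifnot(length(specs) == length(ratios), all(ratios >= 0),
            abs(sum(ratios) - 1) < 1e-9)
  with_seed(seed, {
    counts <- drop(stats::rmultinom(1, n_total, ratios))
    seeds <- sample.int(1e6, length(specs) + 1)
    pops <- lapply(seq_along(specs), function(i) {
      if (counts[i] == 0) return(NULL)
      generate_population(specs[[i]], library, n_cells = counts[i],
                          seed = seeds[i])
    })
    all <- do.call(rbind, pops[!vapply(pops, is.null, TRUE)])
    ord <- sample.int(nrow(all))
    all <- all[ord, ]
    labels <- all$label
    truth <- counts / n_total
    names(truth) <- vapply(specs, function(s) s$class_name, "")
    list(records = all[, setdiff(names(all), "label")], truth = truth,
         labels = labels)
  })
}

#' End-to-end mixture-deconvolution benchmark
#'
#' Trains a random forest on equal-size monodisperse populations of the
#' three cell classes and evaluates mixture-proportion recovery on the
#' five benchmark volume ratios (spherocyte : echinocyte : normal), in
#' both feature modes (30 Mueller elements and 6 PFPs).
#'
#' @param library \code{mm_library} holding the three classes
#' @param n_train training cells per class
#' @param n_test cells per test mixture
#' @param ratios_list list of named length-3 ratio vectors; default the
#'   five benchmark mixtures
#' @param n_trees forest size
#' @param seed RNG seed
#' @return data.frame: mixture, feature mode, absolute error (AE), and
#'   the realized/estimated proportions
#' @export
mixture_benchmark <- function(library, n_train = 2000, n_test = 500,
                              ratios_list = NULL, n_trees = 200,
                              seed = 1) {
  classes <- c("spherocyte", "echinocyte", "normal")
  stopifnot(all(classes %in% names(library$classes)))
  specs <- lapply(library$classes[classes], function(e) e$spec)
  if (is.null(ratios_list))
    ratios_list <- list(c(0.25, 0.25, 0.5), c(0.3, 0.2, 0.5),
                        c(0.1, 0.5, 0.4), c(0.4, 0.4, 0.2),
                        c(0.2, 0.3, 0.5))
  train <- do.call(rbind, lapply(seq_along(specs), function(i)
    generate_population(specs[[i]], library, n_cells = n_train,
                        seed = seed + i)))
  train_pfp <- records_to_pfp(train)
  rf_mm <- train_forest(train, n_trees = n_trees, seed = seed)
  rf_pfp <- train_forest(train_pfp, n_trees = n_trees, seed = seed)
  out <- list()
  for (i in seq_along(ratios_list)) {
    ratios <- ratios_list[[i]]
    mix <- build_mixture(specs, ratios, n_test, library,
                         seed = seed + 100 + i)
    est_mm <- predict_proportions(rf_mm, mix$records)
    est_pfp <- predict_proportions(rf_pfp, records_to_pfp(mix$records))
    tag <- paste(ratios, collapse = ":")
    out[[length(out) + 1]] <- data.frame(
      mixture = tag, mode = c("mm30", "pfp6"),
      ae = c(absolute_error(mix$truth, est_mm),
             absolute_error(mix$truth, est_pfp)))
  }
  do.call(rbind, out)
}
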