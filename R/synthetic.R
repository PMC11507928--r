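#' Configuration for the synthetic cube generator
#'
#' Defines the acquisition geometry and noise structure of simulated
#' hyperspectral scans of oil-filled dishes. Defaults emulate a typical
#' NIR line-scan acquisition: 248 bands over 870-1720 nm, a circular dish
#' on a dark background, three replicate scans averaged per sample.
#'
#' @param n_bands number of spectral bands (>= 8).
#' @param wavelength_range numeric length-2, nm span of the sensor.
#' @param n_samples_per_grade samples simulated per grade.
#' @param cube_shape integer length-2, (rows, cols) of a scan.
#' @param dish_radius dish radius in pixels; must fit inside `cube_shape`.
#' @param replicate_scans scans averaged per sample.
#' @param noise_sd per-pixel per-band additive noise, reflectance units.
#' @param edge_noise extra noise amplification toward the spectral edges
#'   (detector sensitivity falls off at the ends of the range, as in
#'   InGaAs line-scan cameras): the per-band noise sd is multiplied by
#'   `1 + edge_noise * exp(-dist_to_edge / (edge_width * range))`. Edge
#'   bands are therefore nearly pure noise, and wavelength selection has a
#'   real job to do; set 0 for spectrally flat noise.
#' @param edge_width e-folding width of the edge-noise falloff, as a
#'   fraction of the wavelength range.
#' @param scan_noise_sd sd of the per-scan per-band intensity offset
#'   (illumination/detector flicker common to all pixels of a scan line;
#'   unlike pixel noise it does not average out over the ROI, only over
#'   replicate scans). Amplified toward the spectral edges like
#'   `noise_sd`.
#' @param sample_gain_sd sd of the per-sample multiplicative gain
#'   (sample-to-sample brightness variation; removed by scatter
#'   correction such as SNV).
#' @param depth_jitter_sd sd of the per-sample multiplicative jitter on
#'   each absorption-peak depth (sample-to-sample chemistry variation;
#'   survives scatter correction and is the main source of spectral
#'   confusion between the close grades 1 and 2).
#' @param background reflectance of the flat background signature.
#' @param separation_factor required ratio of between-grade mean-spectrum
#'   distance to within-grade spectral noise scale (class-signal contract).
#' @param seed integer; fully determines all generator output.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_bands = 248L,
                             wavelength_range = c(870, 1720),
                             n_samples_per_grade = 20L,
                             cube_shape = c(96L, 96L),
                             dish_radius = 36L,
                             replicate_scans = 3L,
                             noise_sd = 0.01,
                             edge_noise = 12,
                             edge_width = 0.08,
                             scan_noise_sd = 0,
                             sample_gain_sd = 0.01,
                             depth_jitter_sd = 0.05,
                             background = 0.05,
                             separation_factor = 3,
                             seed = 1L) {
  n_bands <- as.integer(n_bands)
  if (n_bands < 8L) stop("n_bands must be >= 8")
  if (length(wavelength_range) != 2L || diff(wavelength_range) <= 0)
    stop("wavelength_range must be an increasing (lo, hi) pair in nm")
  cube_shape <- as.integer(cube_shape)
  if (2 * dish_radius + 2 > min(cube_shape))
    stop("dish (radius ", dish_radius, ") does not fit inside cube_shape")
  if (noise_sd < 0 || sample_gain_sd < 0) stop("noise sds must be >= 0")
  structure(list(n_bands = n_bands,
                 wavelength_range = as.numeric(wavelength_range),
                 n_samples_per_grade = as.integer(n_samples_per_grade),
                 cube_shape = cube_shape,
                 dish_radius = dish_radius,
                 replicate_scans = as.integer(replicate_scans),
                 noise_sd = noise_sd,
                 edge_noise = edge_noise,
                 edge_width = edge_width,
                 scan_noise_sd = scan_noise_sd,
                 sample_gain_sd = sample_gain_sd,
                 depth_jitter_sd = depth_jitter_sd,
                 background = background,
                 separation_factor = separation_factor,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_config> %d bands %.0f-%.0f nm, ",
                     "%d samples/grade, %dx%d px, r=%d, %d scans\n"),
              x$n_bands, x$wavelength_range[1], x$wavelength_range[2],
              x$n_samples_per_grade, x$cube_shape[1], x$cube_shape[2],
              x$dish_radius, x$replicate_scans))
  invisible(x)
}

# NIR absorption features of camellia seed oil: C-H overtone/combination
# bands near 960, 1075, 1320, 1510 (weak) and 1585 nm.
.oil_peaks <- c(960, 1075, 1320, 1510, 1585)
.oil_peak_depths <- c(0.10, 0.09, 0.08, 0.03, 0.08)   # relative dip depth
# grade-specific modulation of the relative depth pattern: grades differ in
# band shape (not just offset), so scatter-corrected spectra stay separable;
# grades 1 and 2 are deliberately close in shape
.grade_depth_mod <- rbind(c(1.05, 0.96, 1.05, 1.10, 0.96),
                          c(1.00, 1.00, 1.00, 1.00, 1.00),
                          c(0.85, 1.10, 0.88, 0.70, 1.12))
# Gaussian dip widths (nm). The weak 1510 nm feature is kept narrower so
# it remains a resolvable local minimum beside the strong 1585 nm band.
.peak_width_nm <- c(30, 30, 30, 12, 30)

#' Grade spectral/texture profiles
#'
#' Builds the three grade profiles that drive the generator. Reflectance of
#' grade 3 is strictly above grades 1 and 2 across the whole range; grades
#' 1 and 2 are spectrally close (their separation is mostly textural), so
#' spectral-only models confuse them while fused models need not. Texture
#' parameters are strictly ordered across grades.
#'
#' @param config a [synthetic_config].
#' @return List of three `grade_profile` objects (grade, baseline,
#'   peak_centers, peak_depths, texture_scale, texture_amplitude).
#' @export
make_grade_profiles <- function(config = synthetic_config()) {
  wr <- config$wavelength_range
  if (any(.oil_peaks < wr[1] | .oil_peaks > wr[2]))
    stop("absorption peak centers fall outside wavelength_range")
  baselines <- c(0.42, 0.46, 0.60)
  tex_scale <- c(2, 4, 8)        # spatial correlation length, px
  tex_amp   <- c(0.03, 0.06, 0.10)
  lapply(1:3, function(g) {
    structure(list(grade = g,
                   baseline = baselines[g],
                   peak_centers = .oil_peaks,
                   peak_depths = .oil_peak_depths * .grade_depth_mod[g, ] *
                     baselines[g],
                   peak_width = .peak_width_nm,
                   texture_scale = tex_scale[g],
                   texture_amplitude = tex_amp[g]),
              class = "grade_profile")
  })
}

#' Evaluate a grade profile's expected reflectance curve
#'
#' The noiseless spectrum: a flat baseline with Gaussian absorption dips
#' at each peak center.
#'
#' @param profile a `grade_profile`.
#' @param wavelengths nm vector.
#' @return Numeric reflectance vector, same length as `wavelengths`.
#' @export
profile_curve <- function(profile, wavelengths) {
  r <- rep(profile$baseline, length(wavelengths))
  w <- rep_len(profile$peak_width, length(profile$peak_centers))
  for (k in seq_along(profile$peak_centers)) {
    r <- r - profile$peak_depths[k] *
      exp(-0.5 * ((wavelengths - profile$peak_centers[k]) / w[k])^2)
  }
  r
}

#' @rdname synthetic_config
#' @param config a [synthetic_config].
#' @export
config_wavelengths <- function(config) {
  seq(config$wavelength_range[1], config$wavelength_range[2],
      length.out = config$n_bands)
}

# Smooth a white-noise field to correlation length `scale` pixels by
# separable moving-average convolution (reflected edges), then rescale to
# unit sd. scale <= 1 returns the field unchanged.
.smooth_field <- function(z, scale) {
  if (scale <= 1) return(z)
  w <- max(3L, 2L * as.integer(round(scale)) + 1L)
  k <- rep(1 / w, w)
  pad <- (w - 1L) %/% 2L
  smooth1 <- function(m) {
    mp <- rbind(m[pad:1, , drop = FALSE], m, m[nrow(m):(nrow(m) - pad + 1),
                                               , drop = FALSE])
    out <- apply(mp, 2L, function(col) stats::filter(col, k, sides = 2L))
    out[(pad + 1L):(pad + nrow(m)), , drop = FALSE]
  }
  z <- smooth1(z)
  z <- t(smooth1(t(z)))
  z / stats::sd(as.vector(z))
}

# Per-band noise sd: flat noise_sd amplified toward both spectral edges.
.band_noise_sd <- function(config) {
  wl <- config_wavelengths(config)
  span <- diff(range(wl))
  tau <- (config$edge_width %||% 0.08) * span
  amp <- 1 + (config$edge_noise %||% 0) *
    (exp(-(wl - wl[1]) / tau) +
     exp(-(wl[length(wl)] - wl) / tau))
  config$noise_sd * amp
}

.disk_mask <- function(shape, radius) {
  cr <- (shape[1] + 1) / 2; cc <- (shape[2] + 1) / 2
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (r - cr)^2 + (c_ - cc)^2 <= radius^2
}

#' Simulate one hyperspectral scan of an oil dish
#'
#' Per-pixel spectra inside the dish equal the profile curve times a
#' band-coherent multiplicative texture field (smoothed Gaussian noise with
#' grade-specific correlation length and amplitude) times a per-scan sample
#' gain, plus independent band noise. Background pixels carry a flat
#' low-reflectance signature. Identical seeds give identical cubes.
#'
#' @param profile a `grade_profile`.
#' @param config a [synthetic_config].
#' @param seed integer scan seed.
#' @param gain per-scan multiplicative gain (default drawn from the
#'   configured per-sample gain distribution by the caller; 1 = nominal).
#' @return List with elements `cube` (a [hypercube]) and `mask`
#'   (logical rows x cols ground-truth dish mask).
#' @export
simulate_cube <- function(profile, config, seed, gain = 1) {
  wl <- config_wavelengths(config)
  nr <- config$cube_shape[1]; nc <- config$cube_shape[2]
  nb <- config$n_bands
  mask <- .disk_mask(config$cube_shape, config$dish_radius)
  curve <- profile_curve(profile, wl) * gain
  with_seed(seed, {
    tex <- 1 + profile$texture_amplitude *
      .smooth_field(matrix(rnorm(nr * nc), nr, nc), profile$texture_scale)
    tex[tex < 0.2] <- 0.2   # keep the field physically multiplicative
    cube <- array(config$background, c(nr, nc, nb))
    sd_b <- .band_noise_sd(config)
    edge_amp <- sd_b / config$noise_sd
    if (any(!is.finite(edge_amp))) edge_amp <- rep(1, nb)
    flick <- if ((config$scan_noise_sd %||% 0) > 0)
      rnorm(nb, sd = config$scan_noise_sd * edge_amp) else numeric(nb)
    for (b in seq_len(nb)) {
      plane <- matrix(config$background, nr, nc)
      plane[mask] <- curve[b] * tex[mask]
      plane <- plane + flick[b]
      if (sd_b[b] > 0) plane <- plane + rnorm(nr * nc, sd = sd_b[b])
      cube[, , b] <- plane
    }
    cube[cube < 0] <- 0
    cube[cube > 1.2] <- 1.2
    list(cube = hypercube(cube, wl), mask = mask)
  })
}

#' Simulate a labeled spectral dataset of oil samples
#'
#' For each sample, `replicate_scans` cubes are generated (same sample gain,
#' different scan noise), the ground-truth-masked mean spectrum of each scan
#' is extracted, and the replicate spectra are averaged to give the sample's
#' row, emulating replicate-scan averaging in practice.
#'
#' @param config a [synthetic_config].
#' @param keep_cubes logical; retain the simulated scans (needed for
#'   texture extraction downstream). Default TRUE.
#' @return List with `dataset` (a [spectral_dataset]) and, when
#'   `keep_cubes`, `scans`: per sample a list of `cube`, `mask`, `label`.
#' @export
simulate_dataset <- function(config = synthetic_config(), keep_cubes = TRUE) {
  if (config$n_samples_per_grade < 2L) stop("need >= 2 samples per grade")
  profiles <- make_grade_profiles(config)
  n <- 3L * config$n_samples_per_grade
  wl <- config_wavelengths(config)
  X <- matrix(NA_real_, n, config$n_bands)
  labels <- integer(n); ids <- character(n)
  scans <- if (keep_cubes) vector("list", n) else NULL
  row <- 0L
  for (g in 1:3) for (s in seq_len(config$n_samples_per_grade)) {
    row <- row + 1L
    sample_seed <- config$seed + 7919L * row
    prof <- profiles[[g]]
    gain <- with_seed(sample_seed, {
      prof$peak_depths <- prof$peak_depths *
        (1 + rnorm(length(prof$peak_depths), sd = config$depth_jitter_sd))
      1 + rnorm(1L, sd = config$sample_gain_sd)
    })
    reps <- matrix(NA_real_, config$replicate_scans, config$n_bands)
    kept <- vector("list", config$replicate_scans)
    for (r in seq_len(config$replicate_scans)) {
      sim <- simulate_cube(prof, config,
                           seed = sample_seed + r, gain = gain)
      reps[r, ] <- extract_mean_spectrum(sim$cube, sim$mask)$reflectance
      if (keep_cubes) kept[[r]] <- sim
    }
    X[row, ] <- colMeans(reps)
    labels[row] <- g
    ids[row] <- sprintf("G%d_S%02d", g, s)
    if (keep_cubes)
      scans[[row]] <- list(replicates = kept, label = g, id = ids[row])
  }
  list(dataset = spectral_dataset(X, labels, ids, wl),
       scans = scans)
}
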