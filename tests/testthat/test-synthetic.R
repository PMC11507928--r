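test_that("grade profiles have absorption minima at the oil bands and a
           dominant grade 3", {
  cfg <- synthetic_config()
  wl <- config_wavelengths(cfg)
  profs <- make_grade_profiles(cfg)
  expect_length(profs, 3L)
  band_step <- diff(wl[1:2])
  for (p in profs) {
    curve <- profile_curve(p, wl)
    n <- length(curve)
    local_min <- which(curve[2:(n - 1)] < curve[1:(n - 2)] &
                         curve[2:(n - 1)] < curve[3:n]) + 1L
    for (pk in c(960, 1075, 1320, 1510, 1585))
      expect_lte(min(abs(wl[local_min] - pk)), 1.5 * band_step)
  }
  c1 <- profile_curve(profs[[1]], wl)
  c2 <- profile_curve(profs[[2]], wl)
  c3 <- profile_curve(profs[[3]], wl)
  expect_true(all(c3 > c1) && all(c3 > c2))
  # no-absorption limit: flat at baseline
  flat <- profs[[1]]; flat$peak_depths[] <- 0
  expect_equal(profile_curve(flat, wl), rep(flat$baseline, length(wl)))
  # peak outside range is a configuration error
  expect_error(make_grade_profiles(
    synthetic_config(wavelength_range = c(1000, 1700))), "outside")
})

test_that("simulate_cube honours the noiseless limit, determinism and the
           reflectance range", {
  cfg <- tiny_cube_config(noise_sd = 0, scan_noise_sd = 0)
  profs <- make_grade_profiles(cfg)
  p0 <- profs[[2]]; p0$texture_amplitude <- 0
  sim <- simulate_cube(p0, cfg, seed = 5)
  curve <- profile_curve(p0, config_wavelengths(cfg))
  px <- which(sim$mask, arr.ind = TRUE)[1, ]
  expect_equal(as.numeric(sim$cube$data[px[1], px[2], ]), curve)

  cfg2 <- tiny_cube_config()
  s1 <- simulate_cube(profs[[1]], cfg2, seed = 9)
  s2 <- simulate_cube(profs[[1]], cfg2, seed = 9)
  expect_identical(s1$cube$data, s2$cube$data)
  expect_true(all(s1$cube$data >= 0 & s1$cube$data <= 1.2))
})

test_that("mean in-mask spectrum is unbiased for the profile curve", {
  cfg <- tiny_cube_config()
  pr <- make_grade_profiles(cfg)[[1]]
  curve <- profile_curve(pr, config_wavelengths(cfg))
  means <- sapply(1:30, function(s) {
    sim <- simulate_cube(pr, cfg, seed = 1000 + s)
    extract_mean_spectrum(sim$cube, sim$mask)$reflectance
  })
  mc_mean <- rowMeans(means)
  mc_se <- apply(means, 1L, sd) / sqrt(ncol(means))
  expect_true(all(abs(mc_mean - curve) < 3.5 * mc_se + 1e-6))
})

test_that("simulate_dataset bookkeeping, replicate averaging and class
           separation behave as designed", {
  cfg <- tiny_cube_config(seed = 7)
  cfg$n_samples_per_grade <- 2L
  out <- simulate_dataset(cfg, keep_cubes = FALSE)
  expect_equal(nrow(out$dataset$X), 6L)
  expect_equal(tabulate(out$dataset$labels, 3L), c(2L, 2L, 2L))

  # averaging replicate scans shrinks the per-band variance of a sample's
  # spectrum (variance of a k-scan mean ~ 1/k)
  pr <- make_grade_profiles(cfg)[[1]]
  one_scan <- sapply(1:12, function(s)
    extract_mean_spectrum(simulate_cube(pr, cfg, seed = 200 + s)$cube,
                          simulate_cube(pr, cfg, seed = 200 + s)$mask
                          )$reflectance)
  three_scan <- sapply(1:12, function(s) {
    reps <- sapply(0:2, function(r) {
      sim <- simulate_cube(pr, cfg, seed = 500 + 3 * s + r)
      extract_mean_spectrum(sim$cube, sim$mask)$reflectance
    })
    rowMeans(reps)
  })
  v1 <- apply(one_scan, 1L, var); v3 <- apply(three_scan, 1L, var)
  expect_gt(mean(v1 > v3), 0.8)

  # grade 3 vs grade 1: linearly separable mean spectra (centroid rule)
  cfg2 <- tiny_cube_config(seed = 31)
  cfg2$n_samples_per_grade <- 4L
  ds <- simulate_dataset(cfg2, keep_cubes = FALSE)$dataset
  g13 <- ds$labels %in% c(1L, 3L)
  X <- ds$X[g13, ]; y <- ds$labels[g13]
  m1 <- colMeans(X[y == 1L, , drop = FALSE])
  m3 <- colMeans(X[y == 3L, , drop = FALSE])
  w <- m3 - m1
  scores <- X %*% w
  cut <- mean(c(min(scores[y == 3L]), max(scores[y == 1L])))
  expect_true(all((scores > cut) == (y == 3L)))
})

test_that("between-grade signal exceeds within-grade spread by the
           configured factor", {
  cfg <- tiny_cube_config(seed = 13)
  cfg$n_samples_per_grade <- 6L
  ds <- simulate_dataset(cfg, keep_cubes = FALSE)$dataset
  cent <- t(sapply(1:3, function(g)
    colMeans(ds$X[ds$labels == g, , drop = FALSE])))
  between <- min(dist(cent))
  within <- mean(sapply(1:3, function(g) {
    Xg <- ds$X[ds$labels == g, , drop = FALSE]
    sqrt(mean(rowSums(sweep(Xg, 2L, colMeans(Xg))^2)))
  }))
  expect_gte(between / within, cfg$separation_factor)
})
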