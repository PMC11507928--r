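test_that("segmentation recovers the dish region", {
  cfg <- tiny_cube_config(noise_sd = 0, scan_noise_sd = 0)
  pr <- make_grade_profiles(cfg)[[2]]
  pr$texture_amplitude <- 0
  sim <- simulate_cube(pr, cfg, seed = 2)
  m <- segment_oil_region(sim$cube)
  expect_equal(sum(m & sim$mask) / sum(m | sim$mask), 1.0)

  cfg2 <- tiny_cube_config(seed = 4)
  sim2 <- simulate_cube(make_grade_profiles(cfg2)[[1]], cfg2, seed = 4)
  m2 <- segment_oil_region(sim2$cube)
  expect_gte(sum(m2 & sim2$mask) / sum(m2 | sim2$mask), 0.95)

  flat <- hypercube(array(0.05, c(12, 12, 4)), 1:4)
  expect_error(segment_oil_region(flat), "segmentation failed")
})

test_that("mean-spectrum extraction is an arithmetic mean and linear", {
  cube <- hypercube(array(0, c(2, 2, 3)), 1:3)
  s <- c(1, 2, 3)
  cube$data[1, 1, ] <- s
  cube$data[2, 1, ] <- 3 * s
  one <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(extract_mean_spectrum(cube, one)$reflectance, s)
  two <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(extract_mean_spectrum(cube, two)$reflectance, 2 * s)
  # linearity in the cube values
  cube5 <- cube; cube5$data <- 5 * cube5$data
  expect_equal(extract_mean_spectrum(cube5, two)$reflectance,
               5 * extract_mean_spectrum(cube, two)$reflectance)
  expect_error(extract_mean_spectrum(cube, matrix(FALSE, 2, 2)), "empty")
})

test_that("outlier screening removes planted abnormal samples and only
           them", {
  fix <- make_outlier_fixture(n_per_grade = 12L, outliers = c(1L, 0L, 0L),
                              seed = 11L)
  res <- remove_outliers(fix$dataset)
  expect_identical(res$removed_ids, fix$planted)

  # infinite threshold: identity
  res_inf <- remove_outliers(fix$dataset, threshold_sd = Inf)
  expect_length(res_inf$removed_ids, 0L)
  expect_equal(res_inf$dataset$X, fix$dataset$X)

  expect_error(remove_outliers(fix$dataset, threshold_sd = 0), "> 0")

  # clean synthetic data: never loses more than 20% of a grade
  cfg <- tiny_cube_config(seed = 8)
  cfg$n_samples_per_grade <- 10L
  ds <- simulate_dataset(cfg, keep_cubes = FALSE)$dataset
  cl <- remove_outliers(ds)
  for (g in 1:3)
    expect_lte(sum(cl$removed_ids %in% ds$ids[ds$labels == g]),
               0.2 * sum(ds$labels == g))
})

test_that("Kennard-Stone picks the max-min-distance calibration set", {
  # 1-D points 0..4, select 3: farthest pair {0,4}, then 2
  ks <- kennard_stone_split(matrix(0:4, 5, 1), c(3, 2),
                            standardize = FALSE)
  expect_identical(ks$calibration_idx, c(1L, 3L, 5L))
  expect_identical(ks$prediction_idx, c(2L, 4L))

  # degenerate ratio: everything is calibration
  ks_all <- kennard_stone_split(matrix(rnorm(8), 8, 1), c(1, 0),
                                standardize = FALSE)
  expect_identical(ks_all$calibration_idx, 1:8)

  # permutation invariance of the selected set (on distinct points)
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  ids <- sprintf("s%02d", 1:20)
  base <- kennard_stone_split(X, standardize = FALSE)
  perm <- sample(20)
  shuf <- kennard_stone_split(X[perm, ], standardize = FALSE)
  expect_setequal(ids[base$calibration_idx],
                  ids[perm][shuf$calibration_idx])

  # sizes follow round(n * 3/5) and the split partitions the samples
  set.seed(4)
  X153 <- matrix(rnorm(153 * 3), 153, 3)
  ks153 <- kennard_stone_split(X153, c(3, 2), standardize = FALSE)
  expect_length(ks153$calibration_idx, 92L)
  expect_length(ks153$prediction_idx, 61L)
  expect_setequal(c(ks153$calibration_idx, ks153$prediction_idx), 1:153)
})
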