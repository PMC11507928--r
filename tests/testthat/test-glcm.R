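test_that("quantization bins the masked intensity range linearly", {
  img <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(quantize_gray(img, levels = 2)[, ], img)

  ramp <- matrix(seq(0, 255, length.out = 64), 8, 8)
  q <- quantize_gray(ramp, levels = 4)
  expect_equal(as.vector(table(q)), rep(16, 4))

  # masked-out bright pixel does not stretch the range
  img2 <- matrix(1, 3, 3); img2[2, 2] <- 100
  m <- matrix(TRUE, 3, 3); m[2, 2] <- FALSE
  q2 <- quantize_gray(img2, m, levels = 4)
  expect_true(all(q2[m] == 0))
  expect_true(is.na(q2[2, 2]))
  expect_true(isTRUE(attr(q2, "constant")))
})

test_that("the worked 2x2 example matches the hand derivation", {
  img <- rbind(c(0, 0), c(1, 1))
  h <- glcm(img, d = 1, f = 0, levels = 2)
  expect_equal(unclass(h), rbind(c(0.5, 0), c(0, 0.5)),
               ignore_attr = TRUE)
  st <- texture_stats(h)
  expect_equal(st$contrast, 0)
  expect_equal(st$energy, 0.5)
  expect_equal(st$entropy, log10(2))
  expect_equal(st$correlation, 1.0)
})

test_that("degenerate and uniform co-occurrence matrices give the
           closed-form statistics", {
  # constant image: single diagonal cell = 1
  h <- glcm(matrix(0L, 4, 4), d = 1, f = 0, levels = 2)
  expect_equal(sum(unclass(h)), 1)
  expect_equal(unclass(h)[1, 1], 1)
  st <- texture_stats(h)
  expect_equal(st$contrast, 0)
  expect_equal(st$energy, 1)
  expect_equal(st$entropy, 0)
  expect_equal(st$correlation, 0)  # degenerate-marginal convention

  for (L in c(2, 4, 8)) {
    hu <- matrix(1 / L^2, L, L)
    stu <- texture_stats(hu)
    expect_equal(stu$energy, 1 / L^2)
    expect_equal(stu$entropy, 2 * log10(L))
  }
})

test_that("GLCM equals the brute-force pair-enumeration oracle", {
  set.seed(9)
  for (rep in 1:10) {
    for (levels in c(2, 4, 8)) {
      g <- matrix(sample(0:(levels - 1L), 64, replace = TRUE), 8, 8)
      for (f in c(0, 45, 90, 135)) for (d in 1:2) {
        h <- glcm(g, d = d, f = f, levels = levels)
        ho <- brute_glcm(g, d, f, levels)
        expect_lt(max(abs(unclass(h) - ho)), 1e-12)
        st <- texture_stats(h)
        so <- brute_texture_stats(ho)
        expect_lt(max(abs(c(st$contrast, st$energy, st$entropy,
                            st$correlation) - so)), 1e-12)
        expect_lt(abs(sum(unclass(h)) - 1), 1e-12)
      }
    }
  }
})

test_that("texture vectors have 16 ordered entries with the expected
           symmetries", {
  set.seed(10)
  img <- matrix(runif(400), 20, 20)
  tv <- texture_vector(img, d = 1, levels = 8)
  expect_length(tv, 16L)
  expect_named(tv[1:4], c("contrast_0", "energy_0", "entropy_0",
                          "correlation_0"))

  # transposing the image swaps the 0/90 blocks; the diagonal directions
  # map onto their own reversed pair sets, so their statistics are
  # unchanged (all four statistics are invariant under h -> t(h))
  tvt <- texture_vector(t(img), d = 1, levels = 8)
  expect_equal(unname(tvt[1:4]), unname(tv[9:12]), tolerance = 1e-12)
  expect_equal(unname(tvt[9:12]), unname(tv[1:4]), tolerance = 1e-12)
  expect_equal(unname(tvt[5:8]), unname(tv[5:8]), tolerance = 1e-12)
  expect_equal(unname(tvt[13:16]), unname(tv[13:16]), tolerance = 1e-12)

  # isotropic smooth texture: horizontal and vertical contrast agree on
  # average across realizations
  f1s <- sapply(1:20, function(s) {
    set.seed(700 + s)
    z <- matrix(rnorm(30 * 30), 30, 30)
    z <- (z[-1, -1] + z[-30, -1] + z[-1, -30] + z[-30, -30]) / 4
    v <- texture_vector(z, d = 1, levels = 8)
    c(v[["contrast_0"]], v[["contrast_90"]])
  })
  expect_lt(abs(mean(f1s[1, ]) - mean(f1s[2, ])) / mean(f1s), 0.1)
})

test_that("image PCA produces orthogonal score images with correct
           variance shares", {
  set.seed(12)
  b1 <- matrix(rnorm(100), 10, 10)
  stack <- list(b1, 2 * b1)
  p <- image_pca(stack)
  expect_equal(p$explained_variance_ratio[1], 1.0, tolerance = 1e-10)

  # two channels with a hand-computed 2x2 covariance
  b2 <- matrix(rnorm(100), 10, 10)
  p2 <- image_pca(list(b1, b2))
  ev <- eigen(cov(cbind(as.vector(b1), as.vector(b2))))$values
  expect_equal(p2$explained_variance_ratio, ev / sum(ev),
               tolerance = 1e-10)
  s1 <- as.vector(p2$score_images[[1]])
  s2 <- as.vector(p2$score_images[[2]])
  expect_lt(abs(cor(s1, s2)), 1e-8)

  expect_error(image_pca(list(b1, b2), mask = matrix(FALSE, 10, 10)))
})

test_that("feature fusion concatenates blocks and scales without
           leakage", {
  set.seed(13)
  spec <- matrix(rnorm(5 * 8), 5, 8)
  tex <- matrix(rnorm(5 * 16), 5, 16)
  fused <- fuse_features(spec, tex)
  expect_equal(dim(fused), c(5L, 24L))
  expect_equal(fused[, 1:8], spec)
  expect_error(fuse_features(spec, tex[, 1:10]), "16")

  sc <- fit_minmax_scaler(fused[1:3, ])
  cal <- apply_minmax_scaler(sc, fused[1:3, ])
  expect_equal(apply(cal, 2, min), rep(0, 24), ignore_attr = TRUE)
  expect_equal(apply(cal, 2, max), rep(1, 24), ignore_attr = TRUE)
  prd <- apply_minmax_scaler(sc, fused[4:5, ])
  expect_true(any(prd < 0 | prd > 1))   # out-of-range rows not clipped
})
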