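make_blobs <- function(n_per = 20, gap = 4, sd = 0.4, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(cbind(rnorm(n_per, 0, sd), rnorm(n_per, 0, sd)),
               cbind(rnorm(n_per, gap, sd), rnorm(n_per, gap, sd)),
               cbind(rnorm(n_per, 0, sd), rnorm(n_per, gap, sd)))
    list(X = X, y = rep(1:3, each = n_per))
  })
}

test_that("the GA fitness trace is monotone and the run is seeded", {
  b <- make_blobs(seed = 21)
  cfg <- ga_config(population_size = 8, generations = 6, seed = 5)
  fit1 <- ga_svm(b$X, b$y, cfg)
  expect_true(all(diff(fit1$fitness_history) >= 0))
  fit2 <- ga_svm(b$X, b$y, cfg)
  expect_identical(fit1$hyperparams, fit2$hyperparams)
  expect_identical(fit1$fitness_history, fit2$fitness_history)
  expect_equal(sort(unique(predict(fit1, b$X))), 1:3)
})

test_that("fixed-hyperparameter SVM behaves as a soft-margin RBF
           classifier", {
  # separable 4-point toy, hard-margin limit
  X <- rbind(c(0, 0), c(0, 1), c(5, 5), c(5, 6))
  y <- c(1, 1, 3, 3)
  m <- svm_train(X, y, c = 1e3, g = 0.5)
  expect_equal(predict(m, X), y)

  # training accuracy non-decreasing in the penalty factor
  b <- make_blobs(gap = 1.6, sd = 0.8, seed = 33)
  acc <- vapply(c(0.01, 1, 100), function(cc) {
    mm <- svm_train(b$X, b$y, c = cc, g = 1)
    mean(predict(mm, b$X) == b$y)
  }, 0)
  expect_true(all(diff(acc) >= 0))

  # duplicating training rows leaves the decision function unchanged
  # (checked away from the decision boundary, where tiny numeric
  # differences in the dual solution cannot flip a label)
  bs <- make_blobs(gap = 4, sd = 0.4, seed = 35)
  m1 <- svm_train(bs$X, bs$y, c = 1, g = 1)
  m2 <- svm_train(rbind(bs$X, bs$X), c(bs$y, bs$y), c = 1, g = 1)
  expect_equal(predict(m1, bs$X), predict(m2, bs$X))

  expect_error(svm_train(rbind(c(NA, 1)), 1, 1, 1), "finite")
})

test_that("evaluation implements the accuracy ratio and confusion
           bookkeeping", {
  b <- make_blobs(seed = 41)
  m <- svm_train(b$X, b$y, c = 10, g = 1)
  ev <- evaluate_model(m, b$X, b$y)
  expect_equal(ev$accuracy_percent, round(100 * ev$m1 / ev$m2, 2))
  expect_equal(sum(diag(ev$confusion)), ev$m1)
  expect_equal(sum(ev$confusion), ev$m2)

  # a fixed-output stand-in model lets the arithmetic be checked exactly
  assign("predict.oracle_clf",
         function(object, newdata, ...) object$truth, envir = globalenv())
  on.exit(rm("predict.oracle_clf", envir = globalenv()), add = TRUE)
  perfect <- structure(list(truth = b$y), class = "oracle_clf")
  expect_equal(evaluate_model(perfect, b$X, b$y)$accuracy_percent, 100)

  # 59 of 61 correct: the two-decimal rounding of the accuracy ratio
  b61 <- make_blobs(n_per = 21, seed = 42)
  y61 <- b61$y[1:61]
  pred59 <- y61; wrong <- c(5, 17)
  pred59[wrong] <- ifelse(pred59[wrong] == 1, 2, 1)
  fixed <- structure(list(truth = pred59), class = "oracle_clf")
  ev59 <- evaluate_model(fixed, b61$X[1:61, ], y61)
  expect_equal(ev59$m2, 61)
  expect_equal(ev59$m1, 59)
  expect_equal(ev59$accuracy_percent, 96.72)

  expect_error(evaluate_model(m, b$X[0, ], integer(0)), "empty")
})

test_that("spectral PCA scores cluster grades better after SNV", {
  p <- pca_scores(matrix(rnorm(40 * 3), 40, 3) %*%
                    rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 1)),
                  n_components = 4)
  expect_lt(p$explained_variance_ratio[4], 1e-10)
  expect_lt(abs(cor(p$scores[, 1], p$scores[, 2])), 1e-8)

  # strong multiplicative scatter: the nuisance SNV exists to remove
  cfg <- tiny_cube_config(seed = 17, sample_gain_sd = 0.06)
  cfg$n_samples_per_grade <- 6L
  ds <- simulate_dataset(cfg, keep_cubes = FALSE)$dataset
  raw <- pca_scores(ds, 2)
  snvd <- pca_scores(apply_chain(ds, "SNV"), 2)
  expect_gt(mean_silhouette(snvd$scores, ds$labels),
            mean_silhouette(raw$scores, ds$labels))
})

test_that("improvement arithmetic matches its two conventions", {
  expect_equal(absolute_improvement(88.76, 83.11), 5.65)
  expect_equal(absolute_improvement(96.61, 86.23), 10.38)
  expect_equal(absolute_improvement(50, 50), 0)
  expect_equal(relative_improvement(98.30, 83.11), 18.28)
  expect_equal(relative_improvement(96.61, 86.23), 12.04)
  expect_equal(relative_improvement(70, 70), 0)
  expect_error(relative_improvement(50, 0), "> 0")
})
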