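#' Genetic-algorithm configuration for SVM hyperparameter search
#'
#' The GA searches (c, g) — the soft-margin penalty and the RBF kernel
#' parameter — on a log10 scale, maximizing mean stratified k-fold
#' cross-validated accuracy on the calibration set. Real-coded GA with
#' tournament selection, blend (BLX-alpha) crossover, Gaussian mutation and
#' elitism, so the best fitness is non-decreasing across generations.
#'
#' @param population_size individuals per generation (default 20).
#' @param generations number of generations (default 50).
#' @param crossover_prob blend-crossover probability (default 0.8).
#' @param mutation_prob per-gene Gaussian mutation probability (default 0.1).
#' @param c_range,g_range search ranges for c and g (default 1e-2..1e2).
#' @param cv_folds folds of the fitness cross-validation (default 5).
#' @param elitism individuals carried over unchanged (default 1, >= 1).
#' @param seed integer run seed.
#' @return List of class `ga_config`.
#' @export
ga_config <- function(population_size = 20L, generations = 50L,
                      crossover_prob = 0.8, mutation_prob = 0.1,
                      c_range = c(1e-2, 1e2), g_range = c(1e-2, 1e2),
                      cv_folds = 5L, elitism = 1L, seed = 1L) {
  stopifnot(population_size >= 2L, generations >= 1L,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            all(c_range > 0), all(g_range > 0), elitism >= 1L,
            cv_folds >= 2L)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 c_range = c_range, g_range = g_range,
                 cv_folds = as.integer(cv_folds),
                 elitism = as.integer(elitism),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# Stratified fold assignment: each class spread as evenly as possible.
.stratified_folds <- function(y, k) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    f[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  f
}

.cv_accuracy <- function(X, y, cost, gamma, folds) {
  k <- max(folds)
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L) return(0)
    m <- e1071::svm(X[tr, , drop = FALSE], factor(y[tr]),
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
    pred <- predict(m, X[!tr, , drop = FALSE])
    correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
  }
  100 * correct / length(y)
}

#' Fit a GA-optimized RBF-SVM grading model
#'
#' The package's central fitting function. A real-coded genetic algorithm
#' tunes the SVM penalty factor c and RBF kernel parameter g by maximizing
#' stratified k-fold cross-validated accuracy on the calibration data; the
#' final model is refit on all calibration rows at the best (c, g).
#' Features are min-max scaled to [0, 1] using ranges learned from the
#' calibration rows (prediction rows may fall outside and are not clipped).
#' Multiclass handling is one-vs-one (libsvm).
#'
#' @param x numeric feature matrix (samples x features).
#' @param y grade labels (integer or factor).
#' @param config a [ga_config].
#' @param scale_features learn a [fit_minmax_scaler()] on `x` (default TRUE).
#' @return Object of class `ga_svm`: `hyperparams` (c, g), `model` (the
#'   fitted e1071 SVM), `fitness_history` (best CV accuracy per
#'   generation), `cv_accuracy`, `scaler`, `config`, `levels`.
#' @seealso [evaluate_model()], [predict.ga_svm()]
#' @export
ga_svm <- function(x, y, config = ga_config(), scale_features = TRUE) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite feature values")
  y <- if (is.factor(y)) as.integer(as.character(y)) else as.integer(y)
  if (length(unique(y)) < 2L) stop("need at least 2 classes")
  scaler <- if (scale_features) fit_minmax_scaler(x)
  xs <- if (scale_features) apply_minmax_scaler(scaler, x) else x
  lc <- log10(config$c_range); lg <- log10(config$g_range)
  np <- config$population_size
  with_seed(config$seed, {
    folds <- .stratified_folds(y, config$cv_folds)
    pop <- cbind(runif(np, lc[1], lc[2]), runif(np, lg[1], lg[2]))
    fitness <- apply(pop, 1L, function(ind)
      .cv_accuracy(xs, y, 10^ind[1], 10^ind[2], folds))
    history <- numeric(config$generations)
    for (gen in seq_len(config$generations)) {
      ord <- order(fitness, decreasing = TRUE)
      elite <- pop[ord[seq_len(config$elitism)], , drop = FALSE]
      elite_fit <- fitness[ord[seq_len(config$elitism)]]
      # tournament selection (size 2)
      pick <- function() {
        i <- sample(np, 2L)
        if (fitness[i[1]] >= fitness[i[2]]) i[1] else i[2]
      }
      children <- matrix(0, np, 2L)
      for (j in seq_len(np)) {
        p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
        if (runif(1) < config$crossover_prob) {
          alpha <- 0.5
          lo <- pmin(p1, p2) - alpha * abs(p1 - p2)
          hi <- pmax(p1, p2) + alpha * abs(p1 - p2)
          child <- runif(2L, lo, hi)
        } else child <- p1
        mut <- runif(2L) < config$mutation_prob
        child[mut] <- child[mut] + rnorm(sum(mut), sd = 0.3)
        child[1] <- min(max(child[1], lc[1]), lc[2])
        child[2] <- min(max(child[2], lg[1]), lg[2])
        children[j, ] <- child
      }
      children[seq_len(config$elitism), ] <- elite
      child_fit <- apply(children, 1L, function(ind)
        .cv_accuracy(xs, y, 10^ind[1], 10^ind[2], folds))
      child_fit[seq_len(config$elitism)] <- elite_fit
      pop <- children; fitness <- child_fit
      history[gen] <- max(fitness)
    }
    best <- pop[which.max(fitness), ]
    hp <- list(c = 10^best[1], g = 10^best[2])
    model <- e1071::svm(xs, factor(y), kernel = "radial",
                        cost = hp$c, gamma = hp$g, scale = FALSE)
    structure(list(hyperparams = hp, model = model,
                   fitness_history = history,
                   cv_accuracy = max(fitness),
                   scaler = scaler, config = config,
                   levels = sort(unique(y))),
              class = "ga_svm")
  })
}

#' @export
print.ga_svm <- function(x, ...) {
  cat(sprintf(paste0("<ga_svm> RBF SVM, c = %.4g, g = %.4g ",
                     "(GA-tuned, %d generations); CV accuracy %.2f%%\n"),
              x$hyperparams$c, x$hyperparams$g,
              x$config$generations, x$cv_accuracy))
  invisible(x)
}

#' @export
summary.ga_svm <- function(object, ...) {
  cat("GA-optimized RBF support vector machine\n")
  cat(sprintf("  penalty factor c        : %.4f\n", object$hyperparams$c))
  cat(sprintf("  kernel parameter g      : %.4f\n", object$hyperparams$g))
  cat(sprintf("  cross-validated accuracy: %.2f%% (%d-fold)\n",
              object$cv_accuracy, object$config$cv_folds))
  cat(sprintf("  support vectors         : %d\n", nrow(object$model$SV)))
  cat(sprintf("  GA: %d individuals x %d generations, elitism %d\n",
              object$config$population_size, object$config$generations,
              object$config$elitism))
  invisible(object)
}

#' @param object a fitted `ga_svm`.
#' @param newdata feature matrix on the original (unscaled) scale.
#' @param ... unused.
#' @rdname ga_svm
#' @export
predict.ga_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  xs <- if (!is.null(object$scaler))
    apply_minmax_scaler(object$scaler, newdata) else newdata
  as.integer(as.character(predict(object$model, xs)))
}

#' @param x a fitted `ga_svm`.
#' @rdname ga_svm
#' @export
plot.ga_svm <- function(x, ...) {
  plot(seq_along(x$fitness_history), x$fitness_history, type = "b",
       xlab = "generation", ylab = "best CV accuracy (%)", ...)
  invisible(x)
}

#' Train an RBF-SVM at fixed hyperparameters
#'
#' Soft-margin SVM with kernel `K(u, v) = exp(-g * ||u - v||^2)`, penalty
#' factor `c`, one-vs-one multiclass. No feature scaling is applied here;
#' scale beforehand (see [fit_minmax_scaler()]) or use [ga_svm()].
#'
#' @param x feature matrix.
#' @param y grade labels.
#' @param c penalty factor (> 0).
#' @param g RBF kernel parameter (> 0).
#' @return Object of class `svm_grade` with a `predict` method returning
#'   integer grades.
#' @export
svm_train <- function(x, y, c, g) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite feature values")
  stopifnot(c > 0, g > 0)
  y <- if (is.factor(y)) as.integer(as.character(y)) else as.integer(y)
  m <- e1071::svm(x, factor(y), kernel = "radial", cost = c, gamma = g,
                  scale = FALSE)
  structure(list(model = m, hyperparams = list(c = c, g = g),
                 levels = sort(unique(y))),
            class = "svm_grade")
}

#' @param object a fitted `svm_grade`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @rdname svm_train
#' @export
predict.svm_grade <- function(object, newdata, ...) {
  as.integer(as.character(predict(object$model, as.matrix(newdata))))
}

#' Evaluate a grading model on labeled data
#'
#' Accuracy is the share of correctly classified samples,
#' `100 * m1 / m2` percent, reported rounded half-up to 2 decimals, with
#' the full confusion matrix.
#'
#' @param model a fitted [ga_svm()] (or anything with a `predict` method
#'   returning integer grades).
#' @param x feature matrix.
#' @param y true grade labels.
#' @return Object of class `eval_report`: `m1`, `m2`, `accuracy_percent`,
#'   `confusion` (true x predicted).
#' @export
evaluate_model <- function(model, x, y) {
  if (length(y) == 0L) stop("empty evaluation set")
  pred <- predict(model, x)
  y <- as.integer(y)
  m2 <- length(y)
  m1 <- sum(pred == y)
  lev <- sort(unique(c(y, pred, if (inherits(model, "ga_svm"))
    model$levels)))
  confusion <- table(factor(y, levels = lev), factor(pred, levels = lev))
  structure(list(m1 = m1, m2 = m2,
                 accuracy_percent = round_half_up(100 * m1 / m2, 2),
                 confusion = confusion),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.2f%% (%d/%d correct)\n",
              x$accuracy_percent, x$m1, x$m2))
  print(x$confusion)
  invisible(x)
}

#' PCA scores of a spectral dataset
#'
#' Column-centered PCA of the (preprocessed) spectra, for exploring grade
#' clustering in score space.
#'
#' @param dataset a [spectral_dataset] (or plain matrix).
#' @param n_components components to return (default 3).
#' @return List: `scores` (samples x components), `explained_variance_ratio`,
#'   `labels` (when available).
#' @export
pca_scores <- function(dataset, n_components = 3L) {
  X <- if (inherits(dataset, "spectral_dataset")) dataset$X else
    as.matrix(dataset)
  if (nrow(X) <= n_components) stop("need more samples than components")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  nc <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(nc), drop = FALSE],
       explained_variance_ratio = evr[seq_len(nc)],
       labels = if (inherits(dataset, "spectral_dataset")) dataset$labels)
}

#' Model-comparison arithmetic
#'
#' Two conventions for "improved by" are in circulation: the absolute gain
#' in percentage points, and the relative gain as a percentage of the
#' baseline. Both are provided, each rounded half-up to 2 decimals.
#'
#' @param acc_new,acc_old accuracies in percent (0-100).
#' @return Percentage points (`absolute_improvement`) or percent of the
#'   baseline (`relative_improvement`).
#' @export
absolute_improvement <- function(acc_new, acc_old) {
  stopifnot(acc_new >= 0, acc_new <= 100, acc_old >= 0, acc_old <= 100)
  round_half_up(acc_new - acc_old, 2)
}

#' @rdname absolute_improvement
#' @export
relative_improvement <- function(acc_new, acc_old) {
  if (acc_old <= 0) stop("baseline accuracy must be > 0")
  round_half_up(100 * (acc_new - acc_old) / acc_old, 2)
}
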