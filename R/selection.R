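#' Characteristic-wavelength subset
#'
#' @param indices selected band indices (unique, sorted on construction).
#' @param wavelengths optional nm values for the selected bands.
#' @param total_bands size of the full wavelength set (proportion basis).
#' @return Object of class `wavelength_subset` with `indices`,
#'   `wavelengths`, and `proportion_of_full` (percent, 2 decimals).
#' @export
wavelength_subset <- function(indices, wavelengths = NULL,
                              total_bands = NULL) {
  indices <- sort(unique(as.integer(indices)))
  structure(list(indices = indices,
                 wavelengths = wavelengths,
                 total_bands = total_bands,
                 proportion_of_full = if (!is.null(total_bands))
                   subset_proportion(length(indices), total_bands)),
            class = "wavelength_subset")
}

#' @export
print.wavelength_subset <- function(x, ...) {
  cat(sprintf("<wavelength_subset> %d bands%s\n", length(x$indices),
              if (!is.null(x$proportion_of_full))
                sprintf(" (%.2f%% of %d)", x$proportion_of_full,
                        x$total_bands) else ""))
  if (!is.null(x$wavelengths))
    cat("  ", paste(round(x$wavelengths, 2), collapse = ", "), "\n")
  invisible(x)
}

#' Share of the full wavelength set covered by a selection
#'
#' @param n_selected selected band count (or a [wavelength_subset]).
#' @param total_bands full wavelength count.
#' @return Percentage, rounded half-up to 2 decimals (17 of 153 -> 11.11).
#' @export
subset_proportion <- function(n_selected, total_bands) {
  if (inherits(n_selected, "wavelength_subset"))
    n_selected <- length(n_selected$indices)
  if (total_bands < n_selected) stop("total_bands must be >= selection size")
  round_half_up(100 * n_selected / total_bands, 2)
}

# Build one SPA chain: greedy successive projections starting from column
# `start`, always taking the column with the largest residual norm after
# projecting out the span of the chain so far. Exact duplicates (residual
# norm ~ 0) can never be selected.
.spa_chain <- function(X, start, k_max, tol = 1e-10) {
  p <- ncol(X)
  R <- X
  norms0 <- sqrt(colSums(X^2))
  chain <- integer(0L)
  cur <- start
  for (k in seq_len(k_max)) {
    chain[k] <- cur
    q <- R[, cur]
    nq <- sqrt(sum(q^2))
    if (nq < tol * max(norms0)) { chain <- chain[seq_len(k - 1L)]; break }
    q <- q / nq
    R <- R - q %*% crossprod(q, R)
    nrm <- sqrt(colSums(R^2))
    nrm[chain] <- -1
    nrm[nrm < tol * max(norms0, 1)] <- -1
    if (k == k_max || all(nrm < 0)) break
    cur <- which.max(nrm)
  }
  chain
}

#' Successive projections algorithm (SPA) wavelength selection
#'
#' Builds, for every candidate starting band, a chain of minimally
#' collinear bands by successive orthogonal projections (each new band has
#' the largest norm after projection onto the orthogonal complement of the
#' chain so far). The final (start, size) pair is the one whose
#' least-squares model on the selected bands minimizes RMSE on an internal
#' 70/30 validation hold-out of the provided rows.
#'
#' @param X samples x bands matrix (calibration rows only).
#' @param y_for_validation response used to score candidate subsets; a
#'   numeric vector/matrix or integer grade labels (one-hot coded).
#' @param k_min,k_max candidate subset-size range (default 5-30);
#'   `k_max` must be below both the sample and band counts.
#' @param seed integer; fixes the internal validation split.
#' @param wavelengths optional nm axis for reporting.
#' @param total_bands proportion denominator (defaults to `ncol(X)`).
#' @return A [wavelength_subset] with attribute `"rmse"` (validation RMSE
#'   of the winning subset).
#' @export
spa_select <- function(X, y_for_validation, k_min = 5L, k_max = 30L,
                       seed = 1L, wavelengths = NULL, total_bands = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (k_min > k_max) stop("k_min must be <= k_max")
  k_max <- min(k_max, p, n - 2L)
  if (k_min > k_max) stop("k_min exceeds the feasible subset size")
  Y <- y_for_validation
  if (is.null(dim(Y)) && all(Y == round(Y)) && length(unique(Y)) <= 10L)
    Y <- grade_onehot(as.integer(Y))
  Y <- as.matrix(Y)
  idx_val <- with_seed(seed, sample(n, max(2L, round(0.3 * n))))
  tr <- setdiff(seq_len(n), idx_val)
  best <- list(rmse = Inf, chain = NULL)
  for (start in seq_len(p)) {
    chain <- .spa_chain(X[tr, , drop = FALSE], start, k_max)
    if (length(chain) < k_min) next
    for (k in k_min:length(chain)) {
      sel <- chain[seq_len(k)]
      Xtr <- cbind(1, X[tr, sel, drop = FALSE])
      fit <- tryCatch(qr.solve(Xtr, Y[tr, , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(fit)) next
      pred <- cbind(1, X[idx_val, sel, drop = FALSE]) %*% fit
      rmse <- sqrt(mean((Y[idx_val, , drop = FALSE] - pred)^2))
      if (rmse < best$rmse) best <- list(rmse = rmse, chain = sel)
    }
  }
  if (is.null(best$chain)) stop("SPA found no valid subset")
  out <- wavelength_subset(best$chain,
                           wavelengths = wavelengths[sort(best$chain)],
                           total_bands = total_bands %||% p)
  attr(out, "rmse") <- best$rmse
  out
}

# Exponentially decreasing function: fraction of bands kept at run i of N,
# fixed by r(1) = 1 and r(N) = 2/p.
.cars_edf <- function(p, n_runs) {
  k <- log(p / 2) / (n_runs - 1)
  a <- exp(k)
  function(i) a * exp(-k * i)
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Iterative wavelength elimination driven by PLS regression-coefficient
#' magnitudes. Each run fits PLS on a Monte-Carlo subset of rows using the
#' currently retained bands, keeps the top-weighted bands under an
#' exponentially decreasing retention schedule (100% of bands at run 1 down
#' to 2 bands at the last run), thins further by adaptive reweighted
#' sampling (bands drawn with probability proportional to weight), and
#' records the RMSECV of the survivors. The subset with the smallest
#' RMSECV across the trace wins; the full-band model is recorded as run 0
#' so the winner can never be worse than no selection.
#'
#' @param X samples x bands matrix (calibration rows only).
#' @param Y response matrix/vector, or integer grade labels (one-hot coded).
#' @param n_runs number of elimination runs (>= 2; default 50).
#' @param n_folds CV folds for RMSECV (default 5).
#' @param max_components PLS component cap (default 10).
#' @param mc_fraction Monte-Carlo row fraction per run (default 0.8).
#' @param seed integer; fixes all sampling.
#' @param wavelengths,total_bands reporting, as in [spa_select()].
#' @return List of class `cars_trace`: `runs` (data.frame with run,
#'   retained, rmsecv), `subsets` (band-index list per run), `best_run`,
#'   `subset` (a [wavelength_subset]).
#' @export
cars_select <- function(X, Y, n_runs = 50L, n_folds = 5L,
                        max_components = 10L, mc_fraction = 0.8,
                        seed = 1L, wavelengths = NULL, total_bands = NULL) {
  X <- as.matrix(X)
  if (is.null(dim(Y)) && all(Y == round(Y)) && length(unique(Y)) <= 10L)
    Y <- grade_onehot(as.integer(Y))
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X)
  if (n_runs < 2L) stop("n_runs must be >= 2")
  edf <- .cars_edf(p, n_runs)
  retained <- seq_len(p)
  n_mc <- max(4L, round(mc_fraction * n))
  comp_cap <- function(nb, nr) max(1L, min(max_components, nb, nr - 2L))
  runs <- data.frame(run = integer(), retained = integer(),
                     rmsecv = numeric())
  subsets <- list()
  # run 0: full-band reference
  r0 <- rmsecv(X, Y, comp_cap(p, n), n_folds, seed = seed)
  runs[1L, ] <- list(0L, p, r0)
  subsets[[1L]] <- retained
  with_seed(seed, {
    for (i in seq_len(n_runs)) {
      rows <- sample(n, n_mc)
      a <- comp_cap(length(retained), n_mc)
      fit <- pls_fit(X[rows, retained, drop = FALSE],
                     Y[rows, , drop = FALSE], a)
      w <- sqrt(rowSums(fit$coefficients^2))
      w <- w / sum(w)
      # forced retention under the schedule
      K <- max(2L, min(round(edf(i) * p), length(retained)))
      ord <- order(w, decreasing = TRUE)
      kept_pos <- ord[seq_len(K)]
      # adaptive reweighted sampling among the kept bands
      draw <- sample(kept_pos, K, replace = TRUE, prob = w[kept_pos])
      new_pos <- sort(unique(draw))
      if (length(new_pos) < 2L) new_pos <- sort(kept_pos[1:2])
      retained <- retained[new_pos]
      # same fold seed for every run: subsets compete on identical folds
      cv <- rmsecv(X[, retained, drop = FALSE], Y,
                   comp_cap(length(retained), n), n_folds, seed = seed)
      runs[i + 1L, ] <- list(i, length(retained), cv)
      subsets[[i + 1L]] <- retained
    }
  })
  best <- which.min(runs$rmsecv)
  sel <- subsets[[best]]
  out <- list(runs = runs, subsets = subsets, best_run = runs$run[best],
              subset = wavelength_subset(sel,
                                         wavelengths = wavelengths[sel],
                                         total_bands = total_bands %||% p))
  class(out) <- "cars_trace"
  out
}

#' @export
print.cars_trace <- function(x, ...) {
  cat(sprintf("<cars_trace> %d runs; best run %d: %d bands, RMSECV %.4f\n",
              nrow(x$runs) - 1L, x$best_run,
              length(x$subset$indices),
              min(x$runs$rmsecv)))
  invisible(x)
}

#' @export
plot.cars_trace <- function(x, ...) {
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  plot(x$runs$run, x$runs$retained, type = "s", xlab = "run",
       ylab = "bands retained", ...)
  plot(x$runs$run, x$runs$rmsecv, type = "b", xlab = "run",
       ylab = "RMSECV", ...)
  graphics::abline(v = x$best_run, lty = 2)
  invisible(x)
}
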