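#' Spectral dataset container
#'
#' The samples x bands matrix all chemometric operations work on, with
#' grade labels, sample ids and the shared wavelength axis.
#'
#' @param X numeric matrix, samples x bands.
#' @param labels integer grades in {1, 2, 3}, one per row.
#' @param ids character sample ids, one per row.
#' @param wavelengths nm vector, one per column.
#' @return Object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(X, labels, ids = NULL, wavelengths = NULL) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(X)))
  if (is.null(wavelengths)) wavelengths <- seq_len(ncol(X))
  if (length(labels) != nrow(X) || length(ids) != nrow(X))
    stop("labels and ids must have one entry per row of X")
  if (!all(labels %in% 1:3)) stop("labels must be in {1, 2, 3}")
  if (length(wavelengths) != ncol(X))
    stop("wavelengths must have one entry per column of X")
  structure(list(X = X, labels = labels, ids = as.character(ids),
                 wavelengths = as.numeric(wavelengths)),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d samples x %d bands; grades: %s\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%d=%d", 1:3, tabulate(x$labels, 3L)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$X)

.subset_dataset <- function(ds, idx) {
  spectral_dataset(ds$X[idx, , drop = FALSE], ds$labels[idx],
                   ds$ids[idx], ds$wavelengths)
}

#' Segment the oil dish region of a cube
#'
#' Thresholds the band-averaged intensity image (Otsu) and keeps the
#' largest connected component, hole-filled. Intended for cubes with a
#' bright circular dish on a darker background.
#'
#' @param cube a [hypercube].
#' @return Logical rows x cols mask with attribute `origin = "segmented"`.
#' @export
segment_oil_region <- function(cube) {
  img <- apply(cube$data, c(1L, 2L), mean)
  rng <- range(img)
  if (diff(rng) < 1e-8)
    stop("segmentation failed: no contrast between region and background")
  norm <- (img - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm))
  bw <- norm > thr
  if (!any(bw)) stop("segmentation failed: nothing above threshold")
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  labm <- EBImage::imageData(lab)
  sizes <- tabulate(labm[labm > 0])
  keep <- which.max(sizes)
  # reject specks: require the region to be a meaningful fraction of frame
  if (sizes[keep] < 0.005 * length(img))
    stop("segmentation failed: no region of meaningful size found")
  comp <- EBImage::fillHull(EBImage::Image((labm == keep) * 1))
  mask <- EBImage::imageData(comp) > 0
  structure(mask, origin = "segmented")
}

#' Mean spectrum over a masked region
#'
#' @param cube a [hypercube].
#' @param mask logical rows x cols; at least one TRUE pixel.
#' @param sample_id optional id carried on the result.
#' @return List of class `spectrum`: wavelengths, reflectance, sample_id.
#' @export
extract_mean_spectrum <- function(cube, mask, sample_id = "") {
  if (!any(mask)) stop("mask is empty")
  d <- dim(cube$data)
  if (!all(dim(mask) == d[1:2])) stop("mask dimensions do not match cube")
  m <- matrix(cube$data, d[1L] * d[2L], d[3L])
  structure(list(wavelengths = cube$wavelengths,
                 reflectance = colMeans(m[as.vector(mask), , drop = FALSE]),
                 sample_id = sample_id),
            class = "spectrum")
}

# Row-wise SNV used by the outlier rule and the K-S distance metric.
.snv_rows <- function(X) t(apply(X, 1L, snv))

#' Remove abnormal samples by standardized spectral distance
#'
#' Within each grade, every spectrum is standardized (SNV) and its
#' Euclidean distance to the grade's mean standardized spectrum computed.
#' Samples whose distance exceeds `center + threshold_sd * scale` are
#' flagged. By default center/scale are the robust median and scaled MAD of
#' the distances, so that a cluster of genuine outliers cannot inflate the
#' cutoff and mask itself; the scale is floored at 10% of the median
#' distance so a grade whose spectra agree to measurement resolution is
#' never decimated on cosmetic differences. `method = "classic"` uses the
#' plain mean and sd of the distances.
#'
#' @param dataset a [spectral_dataset] with >= 3 samples per grade.
#' @param threshold_sd positive cutoff multiplier (default 2.5).
#' @param method `"robust"` (median/MAD, default) or `"classic"` (mean/sd).
#' @return List: `dataset` (cleaned), `removed_ids`, `distances` (named).
#' @export
remove_outliers <- function(dataset, threshold_sd = 2.5,
                            method = c("robust", "classic")) {
  if (threshold_sd <= 0) stop("threshold_sd must be > 0")
  method <- match.arg(method)
  keep <- rep(TRUE, nrow(dataset$X))
  dist_all <- setNames(numeric(nrow(dataset$X)), dataset$ids)
  for (g in sort(unique(dataset$labels))) {
    idx <- which(dataset$labels == g)
    if (length(idx) < 3L) stop("need >= 3 samples in grade ", g)
    Z <- .snv_rows(dataset$X[idx, , drop = FALSE])
    ctr <- colMeans(Z)
    d <- sqrt(rowSums(sweep(Z, 2L, ctr)^2))
    dist_all[idx] <- d
    if (method == "robust") {
      # mad() is 1.4826-scaled; the scale is floored at 10% of the median
      # distance so that a tightly concentrated clean grade (spread at
      # measurement resolution) is not flagged on cosmetic fluctuations
      cut <- median(d) + threshold_sd * max(mad(d), 0.1 * median(d))
    } else {
      cut <- mean(d) + threshold_sd * sd(d)
    }
    keep[idx] <- d <= cut
  }
  list(dataset = .subset_dataset(dataset, which(keep)),
       removed_ids = dataset$ids[!keep],
       distances = dist_all)
}

#' Kennard-Stone calibration/prediction split
#'
#' Classic max-min selection: the first two picks are the globally farthest
#' pair; each later pick maximizes its minimum Euclidean distance to the
#' already-selected set. The most spread-out samples land in the calibration
#' set. Distances are computed on SNV-standardized spectra by default
#' (consistent with the outlier rule); ties break toward the lowest row
#' index, so the split is deterministic and permutation-invariant up to
#' exact ties.
#'
#' @param dataset a [spectral_dataset] with >= 4 samples.
#' @param ratio length-2 integer ratio (calibration : prediction),
#'   default `c(3, 2)`; calibration size is `round(n * r1 / (r1 + r2))`.
#' @param standardize SNV-standardize rows before computing distances.
#' @return List of class `ks_split`: `calibration_idx`, `prediction_idx`,
#'   `ratio`.
#' @export
kennard_stone_split <- function(dataset, ratio = c(3, 2),
                                standardize = TRUE) {
  X <- if (inherits(dataset, "spectral_dataset")) dataset$X else
    as.matrix(dataset)
  n <- nrow(X)
  if (n < 4L) stop("need >= 4 samples to split")
  if (length(ratio) != 2L || any(ratio < 0) || sum(ratio) == 0)
    stop("ratio must be a nonnegative (calibration, prediction) pair")
  n_cal <- as.integer(round(n * ratio[1L] / sum(ratio)))
  if (ratio[2L] == 0) n_cal <- n
  if (standardize && ncol(X) > 1L) X <- .snv_rows(X)
  D <- as.matrix(stats::dist(X))
  sel <- integer(n_cal)
  if (n_cal >= 1L) {
    # farthest pair, lowest-index tie-break via which.max on column-major D
    far <- which(D == max(D), arr.ind = TRUE)
    pair <- sort(far[1L, ])
    if (n_cal == 1L) sel <- pair[1L] else sel[1:2] <- pair
    k <- min(n_cal, 2L)
    mind <- pmin(D[, sel[1L]], if (k == 2L) D[, sel[2L]] else Inf)
    while (k < n_cal) {
      mind[sel[seq_len(k)]] <- -1
      nxt <- which.max(mind)      # ties -> lowest index
      k <- k + 1L
      sel[k] <- nxt
      mind <- pmin(mind, D[, nxt])
    }
  }
  sel <- sort(sel)
  structure(list(calibration_idx = sel,
                 prediction_idx = setdiff(seq_len(n), sel),
                 ratio = ratio),
            class = "ks_split")
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("<ks_split> %d calibration / %d prediction (ratio %d:%d)\n",
              length(x$calibration_idx), length(x$prediction_idx),
              x$ratio[1], x$ratio[2]))
  invisible(x)
}
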