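#' Quantize an image to gray levels over a masked region
#'
#' Linear binning of the in-mask intensity range into `levels` equal-width
#' bins, coded 0..levels-1. Out-of-mask pixels are set to NA. A constant
#' in-mask image quantizes to all zeros (flagged with attribute
#' `"constant"`).
#'
#' @param image numeric matrix.
#' @param mask logical matrix, same shape; at least one TRUE pixel.
#' @param levels number of gray levels (>= 2; default 64).
#' @return Integer matrix of gray levels with NA outside the mask.
#' @export
quantize_gray <- function(image, mask = NULL, levels = 64L) {
  if (levels < 2L) stop("levels must be >= 2")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  if (!any(mask)) stop("mask is empty")
  v <- image[mask]
  r <- range(v)
  g <- matrix(NA_integer_, nrow(image), ncol(image))
  if (diff(r) == 0) {
    g[mask] <- 0L
    attr(g, "constant") <- TRUE
    return(g)
  }
  idx <- as.integer(floor((image[mask] - r[1L]) / diff(r) * levels))
  idx[idx == levels] <- levels - 1L   # max value lands in the top bin
  g[mask] <- idx
  g
}

# Pixel displacement (drow, dcol) for direction f at distance d.
# 0 deg: along the row to the right; angles measured counter-clockwise.
.glcm_offset <- function(d, f) {
  switch(as.character(f),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("direction must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Normalized counts of ordered gray-level pairs (i, j) over pixel pairs
#' (p, p + offset) with both endpoints inside the mask, where the offset is
#' distance `d` along direction `f` in {0, 45, 90, 135} degrees. Entry
#' (i, j) is the probability that a pixel of level i has a pixel of level j
#' at that displacement. Counting is asymmetric (ordered pairs);
#' `symmetric = TRUE` also counts the reverse displacement.
#'
#' @param gray integer gray-level matrix (NA outside the region), as from
#'   [quantize_gray()].
#' @param d offset distance in pixels (>= 1).
#' @param f direction in degrees: 0, 45, 90 or 135.
#' @param levels number of gray levels (default `max(gray) + 1`).
#' @param symmetric count unordered pairs (default FALSE).
#' @return `levels x levels` matrix of class `glcm_matrix`, entries summing
#'   to 1, with attributes `d`, `f`, `levels`.
#' @export
glcm <- function(gray, d = 1L, f = 0L, levels = NULL, symmetric = FALSE) {
  if (d < 1L) stop("d must be >= 1")
  if (is.null(levels)) levels <- max(gray, na.rm = TRUE) + 1L
  off <- .glcm_offset(as.integer(d), f)
  nr <- nrow(gray); nc <- ncol(gray)
  r1 <- max(1L, 1L - off[1L]):min(nr, nr - off[1L])
  c1 <- max(1L, 1L - off[2L]):min(nc, nc - off[2L])
  a <- gray[r1, c1, drop = FALSE]
  b <- gray[r1 + off[1L], c1 + off[2L], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no valid pixel pair under the mask at this offset")
  i <- a[ok]; j <- b[ok]
  h <- matrix(0, levels, levels)
  tab <- table(factor(i, levels = 0:(levels - 1L)),
               factor(j, levels = 0:(levels - 1L)))
  h <- matrix(as.numeric(tab), levels, levels)
  if (symmetric) h <- h + t(h)
  h <- h / sum(h)
  structure(h, class = c("glcm_matrix", "matrix"), d = d, f = f,
            levels = levels)
}

#' GLCM texture statistics: contrast, energy, entropy, correlation
#'
#' The four co-occurrence statistics, with gray levels indexed 0..L-1:
#' contrast `f1 = sum (i-j)^2 h(i,j)`; energy `f2 = sum h(i,j)^2`;
#' entropy `f3 = -sum h(i,j) log10 h(i,j)` over nonzero cells; correlation
#' `f4 = (sum i*j*h(i,j) - mu_x*mu_y) / (sigma_x*sigma_y)` with mu/sigma
#' the marginal means and standard deviations of h, and `f4 = 0` by
#' convention when either marginal is degenerate.
#'
#' @param h a `glcm_matrix` (any nonnegative matrix summing to 1).
#' @param entropy_base base of the entropy logarithm: 10 (default), 2,
#'   or `exp(1)`.
#' @return Named list: `contrast`, `energy`, `entropy`, `correlation`,
#'   plus marginal `means` and `sds`.
#' @export
texture_stats <- function(h, entropy_base = 10) {
  h <- unclass(h)
  L <- nrow(h)
  lev <- 0:(L - 1L)
  I <- matrix(lev, L, L)
  J <- matrix(lev, L, L, byrow = TRUE)
  f1 <- sum((I - J)^2 * h)
  f2 <- sum(h^2)
  nz <- h > 0
  f3 <- -sum(h[nz] * log(h[nz], base = entropy_base))
  px <- rowSums(h); py <- colSums(h)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
  f4 <- if (sx * sy == 0) 0 else (sum(I * J * h) - mux * muy) / (sx * sy)
  list(contrast = f1, energy = f2, entropy = f3, correlation = f4,
       means = c(mux, muy), sds = c(sx, sy))
}

#' 16-element GLCM texture vector of an image
#'
#' Quantizes the masked image and extracts the four statistics at the four
#' directions, concatenated direction-major:
#' (0, 45, 90, 135 degrees) x (contrast, energy, entropy, correlation).
#'
#' @param image numeric matrix.
#' @param mask logical matrix (NULL = whole image).
#' @param d offset distance (default 1).
#' @param levels gray levels (default 64).
#' @param symmetric passed to [glcm()].
#' @return Named numeric vector of length 16.
#' @export
texture_vector <- function(image, mask = NULL, d = 1L, levels = 64L,
                           symmetric = FALSE) {
  g <- quantize_gray(image, mask, levels)
  out <- numeric(0)
  for (f in c(0L, 45L, 90L, 135L)) {
    st <- texture_stats(glcm(g, d = d, f = f, levels = levels,
                             symmetric = symmetric))
    v <- c(st$contrast, st$energy, st$entropy, st$correlation)
    names(v) <- paste0(c("contrast", "energy", "entropy", "correlation"),
                       "_", f)
    out <- c(out, v)
  }
  out
}

#' Pixelwise PCA of a stack of band images
#'
#' Treats each in-mask pixel as an observation with one value per channel,
#' performs column-centered PCA, and folds the component scores back into
#' score images (NA outside the mask).
#'
#' @param stack list of numeric matrices (same shape), or a rows x cols x k
#'   array, k >= 2.
#' @param mask logical matrix (NULL = whole image).
#' @param n_components components to keep (default all).
#' @return List of class `pc_score_stack`: `score_images`,
#'   `explained_variance_ratio`, `n_components`.
#' @export
image_pca <- function(stack, mask = NULL, n_components = NULL) {
  if (is.list(stack)) stack <- simplify2array(stack)
  stopifnot(length(dim(stack)) == 3L)
  k <- dim(stack)[3L]
  if (k < 2L) stop("need at least 2 channels")
  if (is.null(mask)) mask <- matrix(TRUE, dim(stack)[1L], dim(stack)[2L])
  npix <- sum(mask)
  if (k > npix) stop("more channels than in-mask pixels")
  M <- matrix(NA_real_, npix, k)
  for (b in seq_len(k)) M[, b] <- stack[, , b][mask]
  pc <- prcomp(M, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  nc <- min(n_components %||% k, ncol(pc$x))
  imgs <- lapply(seq_len(nc), function(a) {
    im <- matrix(NA_real_, nrow(mask), ncol(mask))
    im[mask] <- pc$x[, a]
    im
  })
  structure(list(score_images = imgs,
                 explained_variance_ratio = evr[seq_len(nc)],
                 n_components = nc),
            class = "pc_score_stack")
}

#' Min-max feature scaler (fit on calibration rows only)
#'
#' @param X calibration feature matrix.
#' @return Object of class `minmax_scaler`.
#' @export
fit_minmax_scaler <- function(X) {
  X <- as.matrix(X)
  lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
  span <- hi - lo
  span[span == 0] <- 1   # constant feature maps to 0
  structure(list(lo = lo, span = span), class = "minmax_scaler")
}

#' @param scaler a `minmax_scaler`.
#' @param X feature matrix to transform. Rows outside the calibration range
#'   may map outside [0, 1]; they are not clipped.
#' @rdname fit_minmax_scaler
#' @export
apply_minmax_scaler <- function(scaler, X) {
  sweep(sweep(as.matrix(X), 2L, scaler$lo), 2L, scaler$span, "/")
}

#' Fuse spectral and texture features
#'
#' Concatenates the spectral block (values at the selected characteristic
#' wavelengths) with the 16-element texture vector, spectral block first.
#' Scaling is the caller's responsibility (fit a [fit_minmax_scaler()] on
#' calibration rows only).
#'
#' @param spectral numeric matrix/vector of spectral features.
#' @param texture numeric matrix/vector of texture features (16 per row).
#' @return The fused feature matrix.
#' @export
fuse_features <- function(spectral, texture) {
  spectral <- rbind(spectral); texture <- rbind(texture)
  if (nrow(spectral) != nrow(texture))
    stop("spectral and texture row counts differ")
  if (ncol(texture) != 16L)
    stop("texture block must have 16 columns, got ", ncol(texture))
  cbind(spectral, texture)
}
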