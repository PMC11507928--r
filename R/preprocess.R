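#' Standard normal variate
#'
#' Per-spectrum standardization to zero mean and unit sample (n-1) standard
#' deviation; removes multiplicative scatter and baseline offsets.
#'
#' @param x numeric spectrum, length >= 2, non-constant.
#' @return Standardized spectrum.
#' @export
snv <- function(x) {
  if (length(x) < 2L) stop("SNV needs at least 2 bands")
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("SNV undefined for a constant spectrum")
  (x - mean(x)) / s
}

#' Min-max normalization to [0, 1]
#'
#' @param x numeric spectrum with max > min.
#' @return `(x - min) / (max - min)`.
#' @export
normalize_minmax <- function(x) {
  r <- range(x)
  if (r[2L] <= r[1L]) stop("normalize undefined for a constant spectrum")
  (x - r[1L]) / (r[2L] - r[1L])
}

#' Savitzky-Golay filtering and derivatives
#'
#' Least-squares local-polynomial convolution smoothing; `deriv = 1` or `2`
#' returns the first/second derivative with respect to band index. Edges are
#' handled by polynomial fits within the terminal windows (as in
#' [signal::sgolayfilt()]).
#'
#' @param x numeric spectrum.
#' @param window odd window length, `polyorder < window <= length(x)`.
#' @param polyorder polynomial degree.
#' @param deriv derivative order 0, 1 or 2.
#' @return Filtered spectrum, same length as `x`.
#' @export
sg_filter <- function(x, window = 11L, polyorder = 2L, deriv = 0L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  if (window > length(x)) stop("window exceeds spectrum length")
  if (!deriv %in% 0:2) stop("deriv must be 0, 1 or 2")
  if (deriv > polyorder) stop("deriv must be <= polyorder")
  as.numeric(signal::sgolayfilt(x, p = polyorder, n = window, m = deriv))
}

#' Preprocessing chain
#'
#' An ordered list of named steps from the closed set {`SG`, `Normalize`,
#' `SNV`, `1Der`, `2Der`}. `SG` accepts `window`/`polyorder`; `1Der`/`2Der`
#' are Savitzky-Golay derivatives (window 11, polyorder 2 and 3 by default)
#' unless `finite_diff = TRUE` requests plain differencing.
#'
#' @param ... step names as character strings, or named lists
#'   `list(name = "SG", window = 11, polyorder = 2)`.
#' @return Object of class `preprocess_chain`.
#' @examples
#' preprocess_chain("SG", "SNV")
#' preprocess_chain(list(name = "SG", window = 7, polyorder = 3), "1Der")
#' @export
preprocess_chain <- function(...) {
  steps <- lapply(list(...), function(s) {
    if (is.character(s)) s <- list(name = s)
    if (is.null(s$name)) stop("each step needs a name")
    s$name <- match.arg(s$name, c("SG", "Normalize", "SNV", "1Der", "2Der"))
    s
  })
  structure(list(steps = steps), class = "preprocess_chain")
}

#' @export
print.preprocess_chain <- function(x, ...) {
  nm <- vapply(x$steps, `[[`, "", "name")
  cat("<preprocess_chain>",
      if (length(nm)) paste(nm, collapse = " -> ") else "(identity)", "\n")
  invisible(x)
}

.apply_step <- function(x, step) {
  switch(step$name,
    SG = sg_filter(x, step$window %||% 11L, step$polyorder %||% 2L, 0L),
    Normalize = normalize_minmax(x),
    SNV = snv(x),
    `1Der` = if (isTRUE(step$finite_diff)) c(diff(x), 0) else
      sg_filter(x, step$window %||% 11L, step$polyorder %||% 2L, 1L),
    `2Der` = if (isTRUE(step$finite_diff)) c(diff(x, differences = 2L), 0, 0)
      else sg_filter(x, step$window %||% 11L, step$polyorder %||% 3L, 2L))
}

#' Apply a preprocessing chain to a dataset
#'
#' Steps run row-wise in order; each sample is transformed independently
#' (no statistics shared across rows), so preprocessing is identical for
#' calibration and prediction sets and cannot leak split information.
#' Wavelengths and labels are untouched.
#'
#' @param dataset a [spectral_dataset].
#' @param chain a [preprocess_chain] (or character vector of step names).
#' @return The transformed [spectral_dataset].
#' @export
apply_chain <- function(dataset, chain) {
  if (is.character(chain)) chain <- do.call(preprocess_chain,
                                            as.list(chain))
  stopifnot(inherits(chain, "preprocess_chain"))
  X <- dataset$X
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    for (step in chain$steps) {
      x <- tryCatch(.apply_step(x, step),
                    error = function(e) stop("row '", dataset$ids[i], "': ",
                                             conditionMessage(e)))
    }
    X[i, ] <- x
  }
  spectral_dataset(X, dataset$labels, dataset$ids, dataset$wavelengths)
}
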