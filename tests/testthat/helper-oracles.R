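# Brute-force GLCM oracle: explicit enumeration of ordered pixel pairs.
# Independent of the package's vectorized implementation.
brute_glcm <- function(gray, d, f, levels) {
  off <- switch(as.character(f),
                "0" = c(0L, d), "45" = c(-d, d),
                "90" = c(-d, 0L), "135" = c(-d, -d))
  h <- matrix(0, levels, levels)
  for (r in seq_len(nrow(gray))) for (cc in seq_len(ncol(gray))) {
    r2 <- r + off[1L]; c2 <- cc + off[2L]
    if (r2 < 1 || r2 > nrow(gray) || c2 < 1 || c2 > ncol(gray)) next
    i <- gray[r, cc]; j <- gray[r2, c2]
    if (is.na(i) || is.na(j)) next
    h[i + 1L, j + 1L] <- h[i + 1L, j + 1L] + 1
  }
  h / sum(h)
}

# Direct-summation oracle for the four texture statistics.
brute_texture_stats <- function(h) {
  L <- nrow(h)
  f1 <- 0; f2 <- 0; f3 <- 0; sij <- 0
  for (i in 0:(L - 1L)) for (j in 0:(L - 1L)) {
    p <- h[i + 1L, j + 1L]
    f1 <- f1 + (i - j)^2 * p
    f2 <- f2 + p^2
    if (p > 0) f3 <- f3 - p * log10(p)
    sij <- sij + i * j * p
  }
  px <- rowSums(h); py <- colSums(h)
  mux <- sum((0:(L - 1L)) * px); muy <- sum((0:(L - 1L)) * py)
  sx <- sqrt(sum(((0:(L - 1L)) - mux)^2 * px))
  sy <- sqrt(sum(((0:(L - 1L)) - muy)^2 * py))
  f4 <- if (sx * sy == 0) 0 else (sij - mux * muy) / (sx * sy)
  c(f1 = f1, f2 = f2, f3 = f3, f4 = f4)
}

# Small synthetic spectral fixture with bounded within-grade variation:
# per-sample depth multiplier is uniform, so the clean distance
# distribution is short-tailed. Planted outliers get grossly distorted
# absorption patterns.
make_outlier_fixture <- function(n_per_grade = 56L,
                                 outliers = c(8L, 7L, 0L), seed = 101L) {
  cfg <- synthetic_config(seed = seed)
  wl <- config_wavelengths(cfg)
  profs <- make_grade_profiles(cfg)
  withr::with_seed(seed, {
    rows <- list(); labels <- integer(0); ids <- character(0)
    planted <- character(0)
    for (g in 1:3) for (s in seq_len(n_per_grade)) {
      pr <- profs[[g]]
      id <- sprintf("G%d_%02d", g, s)
      if (s <= outliers[g]) {
        # gross acquisition fault: absorption pattern tripled and warped
        pr$peak_depths <- pr$peak_depths * c(3, 0.2, 3, 0.2, 3)
        planted <- c(planted, id)
      }
      # clean within-grade variation: multiplicative gain (removed by the
      # SNV standardization inside the rule) + band noise at measurement
      # resolution; standardized distances concentrate tightly
      x <- profile_curve(pr, wl) * (1 + runif(1, -0.02, 0.02)) +
        rnorm(length(wl), sd = 5e-4)
      rows[[length(rows) + 1L]] <- x
      labels <- c(labels, g); ids <- c(ids, id)
    }
    list(dataset = spectral_dataset(do.call(rbind, rows), labels, ids, wl),
         planted = planted)
  })
}

# Small-cube generator settings shared by image-level tests.
tiny_cube_config <- function(seed = 1L, ...) {
  synthetic_config(n_bands = 24L, cube_shape = c(36L, 36L),
                   dish_radius = 13L, n_samples_per_grade = 3L,
                   replicate_scans = 2L, seed = seed, ...)
}

# Mean silhouette width of a labelling in a feature space (euclidean).
mean_silhouette <- function(X, labels) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
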