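#' Experiment configuration
#'
#' One row of the modelling experiment matrix: a data source, a
#' preprocessing chain, a wavelength selector, a texture source and the GA
#' settings. Texture fusion is defined on the CARS characteristic
#' wavelengths, so any texture source other than `"none"` requires
#' `selector = "CARS"`.
#'
#' @param data a [synthetic_config()] (synthetic run), or a pre-built
#'   result of [simulate_dataset()] (reused across matrix rows).
#' @param preprocess a [preprocess_chain()] or character vector of step
#'   names (default `"SNV"`).
#' @param selector `"none"`, `"SPA"` or `"CARS"`.
#' @param texture_source `"none"`, `"raw_bands"`, `"PC1"`, `"PC2"` or
#'   `"PC3"`. `raw_bands` extracts texture from the mean of the selected
#'   band images; `PCk` from the k-th principal-component score image of
#'   the per-sample selected-band stack.
#' @param ga a [ga_config()].
#' @param ratio Kennard-Stone calibration:prediction ratio.
#' @param outlier_threshold passed to [remove_outliers()] (NULL = skip).
#' @param glcm_levels,glcm_d GLCM quantization levels and offset distance.
#' @param seed master seed for the row (selection, GA).
#' @param name row label (default auto-built from the choices).
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(data = synthetic_config(),
                              preprocess = "SNV",
                              selector = c("none", "SPA", "CARS"),
                              texture_source = c("none", "raw_bands",
                                                 "PC1", "PC2", "PC3"),
                              ga = ga_config(),
                              ratio = c(3, 2),
                              outlier_threshold = 2.5,
                              glcm_levels = 64L, glcm_d = 1L,
                              seed = 1L, name = NULL) {
  selector <- match.arg(selector)
  texture_source <- match.arg(texture_source)
  if (texture_source != "none" && selector != "CARS")
    stop("texture fusion is defined on CARS wavelengths; ",
         "texture_source != 'none' requires selector = 'CARS'")
  if (is.character(preprocess))
    preprocess <- do.call(preprocess_chain, as.list(preprocess))
  if (is.null(name)) {
    steps <- vapply(preprocess$steps, `[[`, "", "name")
    name <- paste(c(if (length(steps)) paste(steps, collapse = "+")
                    else "Raw",
                    if (selector != "none") selector,
                    if (texture_source != "none")
                      paste0("GLCM(", texture_source, ")"),
                    "GA-SVM"), collapse = "-")
  }
  structure(list(data = data, preprocess = preprocess, selector = selector,
                 texture_source = texture_source, ga = ga, ratio = ratio,
                 outlier_threshold = outlier_threshold,
                 glcm_levels = as.integer(glcm_levels),
                 glcm_d = as.integer(glcm_d),
                 seed = as.integer(seed), name = name),
            class = "experiment_config")
}

# Per-sample texture vectors from the stored scans at the selected bands.
.sample_textures <- function(scans, band_idx, source, levels, d) {
  t(vapply(scans, function(sc) {
    reps <- sc$replicates
    mask <- reps[[1L]]$mask
    # replicate-averaged images at the selected bands
    imgs <- lapply(band_idx, function(b) {
      acc <- 0
      for (r in reps) acc <- acc + r$cube$data[, , b]
      acc / length(reps)
    })
    img <- if (source == "raw_bands") {
      Reduce(`+`, imgs) / length(imgs)
    } else {
      pc_idx <- as.integer(sub("PC", "", source))
      stack <- image_pca(imgs, mask)
      sc_img <- stack$score_images[[min(pc_idx, stack$n_components)]]
      sc_img
    }
    texture_vector(img, mask, d = d, levels = levels)
  }, numeric(16L)))
}

#' Run one grading experiment end to end
#'
#' Pipeline: simulate/load data, remove abnormal samples, Kennard-Stone
#' split, row-wise preprocessing, wavelength selection on calibration rows
#' only, optional texture extraction and fusion, GA-SVM fit on the
#' calibration set, evaluation on both sets. All randomness derives from
#' the configured seeds.
#'
#' @param config an [experiment_config()].
#' @param output_dir optional directory; when given, the selected subset,
#'   CARS trace, report row and a run manifest are written as delimited
#'   text files.
#' @return Object of class `grade_experiment`: `name`, `hyperparams`,
#'   `calibration` and `prediction` [evaluate_model()] reports, `subset`,
#'   `trace` (CARS only), `split`, `model`, `config`.
#' @export
run_experiment <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  need_cubes <- config$texture_source != "none"
  sim <- if (inherits(config$data, "synthetic_config"))
    simulate_dataset(config$data, keep_cubes = need_cubes)
  else config$data
  ds <- sim$dataset; scans <- sim$scans
  if (need_cubes && is.null(scans))
    stop("stage texture: data source retained no image scans")
  if (!is.null(config$outlier_threshold)) {
    cl <- remove_outliers(ds, config$outlier_threshold)
    keep <- match(cl$dataset$ids, ds$ids)
    ds <- cl$dataset
    if (!is.null(scans)) scans <- scans[keep]
  }
  split <- kennard_stone_split(ds, config$ratio)
  pp <- tryCatch(apply_chain(ds, config$preprocess),
                 error = function(e) stop("stage preprocess: ",
                                          conditionMessage(e)))
  cal <- split$calibration_idx; prd <- split$prediction_idx
  wl <- pp$wavelengths
  subset <- NULL; trace <- NULL
  band_idx <- seq_len(ncol(pp$X))
  if (config$selector == "SPA") {
    subset <- spa_select(pp$X[cal, , drop = FALSE], pp$labels[cal],
                         seed = config$seed, wavelengths = wl,
                         total_bands = ncol(pp$X))
    band_idx <- subset$indices
  } else if (config$selector == "CARS") {
    trace <- cars_select(pp$X[cal, , drop = FALSE], pp$labels[cal],
                         seed = config$seed, wavelengths = wl,
                         total_bands = ncol(pp$X))
    subset <- trace$subset
    band_idx <- subset$indices
  }
  feats <- pp$X[, band_idx, drop = FALSE]
  if (need_cubes) {
    tex <- .sample_textures(scans, band_idx, config$texture_source,
                            config$glcm_levels, config$glcm_d)
    feats <- fuse_features(feats, tex)
  }
  ga <- config$ga; ga$seed <- config$seed
  model <- ga_svm(feats[cal, , drop = FALSE], pp$labels[cal], ga)
  out <- structure(list(
    name = config$name,
    hyperparams = model$hyperparams,
    calibration = evaluate_model(model, feats[cal, , drop = FALSE],
                                 pp$labels[cal]),
    prediction = evaluate_model(model, feats[prd, , drop = FALSE],
                                pp$labels[prd]),
    subset = subset, trace = trace, split = split,
    model = model, config = config), class = "grade_experiment")
  if (!is.null(output_dir)) .write_artifacts(out, output_dir)
  out
}

.write_artifacts <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(res$subset))
    utils::write.table(
      data.frame(index = res$subset$indices,
                 wavelength_nm = res$subset$wavelengths %||% NA),
      file.path(dir, "subset.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
  if (!is.null(res$trace))
    utils::write.table(res$trace$runs, file.path(dir, "cars_trace.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(summary_row(res)),
                     file.path(dir, "report.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(c(paste0("package_version: ",
                      as.character(utils::packageVersion("hsigrade"))),
               paste0("seed: ", res$config$seed),
               paste0("name: ", res$name),
               paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
             file.path(dir, "manifest.txt"))
}

summary_row <- function(res) {
  data.frame(model = res$name,
             penalty_c = res$hyperparams$c,
             kernel_g = res$hyperparams$g,
             calibration_accuracy = res$calibration$accuracy_percent,
             prediction_accuracy = res$prediction$accuracy_percent)
}

#' @export
print.grade_experiment <- function(x, ...) {
  cat(sprintf("<grade_experiment> %s\n", x$name))
  cat(sprintf("  c = %.4g, g = %.4g\n", x$hyperparams$c, x$hyperparams$g))
  cat(sprintf("  calibration accuracy: %.2f%%  (%d/%d)\n",
              x$calibration$accuracy_percent, x$calibration$m1,
              x$calibration$m2))
  cat(sprintf("  prediction accuracy : %.2f%%  (%d/%d)\n",
              x$prediction$accuracy_percent, x$prediction$m1,
              x$prediction$m2))
  if (!is.null(x$subset))
    cat(sprintf("  selected bands: %d (%.2f%% of full)\n",
                length(x$subset$indices), x$subset$proportion_of_full))
  invisible(x)
}

#' Run a matrix of grading experiments on a shared data realization
#'
#' Simulates the data once, removes outliers and computes the
#' Kennard-Stone split once, then runs every row on the identical
#' calibration/prediction membership so model comparisons are paired. The
#' improvement block reports, for each row against the first row, both the
#' absolute gain (percentage points) and the relative gain (percent of
#' baseline).
#'
#' @param rows list of [experiment_config()]s; their `data` fields are
#'   replaced by the shared realization drawn from `base_data`.
#' @param base_data a [synthetic_config()] (or prebuilt
#'   [simulate_dataset()] output) shared by all rows.
#' @return Object of class `grade_matrix`: `table` (one row per model),
#'   `improvements`, `results` (per-row `grade_experiment`s, failed rows
#'   carry the error message).
#' @export
run_matrix <- function(rows, base_data = synthetic_config()) {
  if (length(rows) == 0L) stop("empty experiment list")
  need_cubes <- any(vapply(rows, function(r) r$texture_source != "none",
                           TRUE))
  sim <- if (inherits(base_data, "synthetic_config"))
    simulate_dataset(base_data, keep_cubes = need_cubes)
  else base_data
  results <- vector("list", length(rows))
  tab <- NULL
  for (i in seq_along(rows)) {
    cfg <- rows[[i]]
    cfg$data <- sim
    res <- tryCatch(run_experiment(cfg), error = function(e)
      structure(list(name = cfg$name, error = conditionMessage(e)),
                class = "grade_experiment_error"))
    results[[i]] <- res
    tab <- rbind(tab, if (inherits(res, "grade_experiment_error"))
      data.frame(model = res$name, penalty_c = NA, kernel_g = NA,
                 calibration_accuracy = NA, prediction_accuracy = NA)
      else as.data.frame(summary_row(res)))
  }
  ok <- !is.na(tab$calibration_accuracy)
  improvements <- NULL
  if (sum(ok) >= 2L) {
    base <- which(ok)[1L]
    others <- setdiff(which(ok), base)
    improvements <- do.call(rbind, lapply(others, function(i) data.frame(
      model = tab$model[i], baseline = tab$model[base],
      cal_gain_points = absolute_improvement(
        tab$calibration_accuracy[i], tab$calibration_accuracy[base]),
      pred_gain_points = absolute_improvement(
        tab$prediction_accuracy[i], tab$prediction_accuracy[base]),
      cal_gain_relative_pct = relative_improvement(
        tab$calibration_accuracy[i], tab$calibration_accuracy[base]),
      pred_gain_relative_pct = relative_improvement(
        tab$prediction_accuracy[i], tab$prediction_accuracy[base]))))
  }
  structure(list(table = tab, improvements = improvements,
                 results = results),
            class = "grade_matrix")
}

#' @export
print.grade_matrix <- function(x, ...) {
  cat("<grade_matrix>\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$improvements)) {
    cat("\nImprovement over baseline (points = absolute percentage",
        "points; relative = % of baseline):\n")
    print(x$improvements, row.names = FALSE)
  }
  invisible(x)
}
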