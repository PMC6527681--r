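# Model selection: R2/RMSE of automatic vs manual stomatal density over a
# test set, swept across training-set size and confidence threshold, plus
# the batch-resampling comparison of trained models.

#' Agreement metrics between manual and automatic SD
#'
#' R2 is the squared Pearson correlation of the (manual, automatic) pairs
#' (identical to the OLS coefficient of determination with intercept);
#' RMSE is the root mean squared difference. The slope and intercept of
#' the OLS regression of automatic on manual are reported alongside, as on
#' the usual calibration scatter plots.
#'
#' @param manual_sd,auto_sd equal-length numeric vectors (n >= 2).
#' @return list with `r2`, `rmse`, `slope`, `intercept`, `n`.
#' @export
regression_metrics <- function(manual_sd, auto_sd) {
  if (length(manual_sd) != length(auto_sd)) stopf("vectors must align")
  n <- length(manual_sd)
  if (n < 2L) stopf("at least two pairs are required")
  if (sd(manual_sd) == 0) stopf("manual SD has zero variance; R2 undefined")
  r2 <- if (sd(auto_sd) == 0) 0 else cor(manual_sd, auto_sd)^2
  rmse <- sqrt(mean((auto_sd - manual_sd)^2))
  fit <- coef(lm(auto_sd ~ manual_sd))
  list(r2 = r2, rmse = rmse, slope = unname(fit[2]),
       intercept = unname(fit[1]), n = n)
}

#' The calibrated confidence-threshold axis
#'
#' The protocol sweeps the stomata confidence threshold from 0.10 to 0.95
#' at intervals of 0.05 (18 values).
#'
#' @return numeric vector of thresholds.
#' @export
c_st_axis <- function() seq(0.10, 0.95, by = 0.05)

#' Measure automatic stomatal density over a set of images
#'
#' @param images list of images/scenes accepted by [detect()].
#' @param model a fitted `ssd_model`.
#' @param c_st confidence threshold.
#' @param calibration a [calibration_spec()] (or an imaged area in mm2).
#' @return numeric vector of SD in mm-2, one per image.
#' @export
measure_sd <- function(images, model, c_st, calibration) {
  area <- calibration_area(calibration)
  vapply(images, function(im) count_stomata(im, model, c_st) / area,
         numeric(1))
}

# Detections once per (model, image) at the lowest threshold on the axis;
# counts at higher thresholds are score filters of that result. For greedy
# NMS this is exactly equivalent to re-running detection at each threshold,
# because whether a box is kept depends only on higher-scoring boxes, all
# of which survive any filter the box itself survives.
count_over_thresholds <- function(images, model, c_sts) {
  base <- min(c_sts)
  counts <- matrix(0L, length(images), length(c_sts))
  for (i in seq_along(images)) {
    det <- detect(images[[i]], model, base)
    counts[i, ] <- vapply(c_sts, function(ct) sum(det$score > ct),
                          integer(1))
  }
  counts
}

#' Evaluate models over the training-size x confidence-threshold grid
#'
#' For every (model, c_st) cell, measures automatic SD on the test images
#' via [count_stomata()] and the calibration area, and computes
#' [regression_metrics()] against the manual SD -- the heat-map table used
#' to pick the operating point.
#'
#' @param models a single `ssd_model` or a list of models (one per
#'   training size; names or `n_train` label the size axis).
#' @param c_st_values confidence-threshold axis (default [c_st_axis()]).
#' @param test_images list of test images/scenes.
#' @param manual_sd manual (reference) SD per test image, mm-2.
#' @param calibration [calibration_spec()] or imaged area in mm2.
#' @return an `evaluation_grid` data frame with columns `size`, `c_st`,
#'   `r2`, `rmse`.
#' @export
grid_evaluate <- function(models, c_st_values = c_st_axis(), test_images,
                          manual_sd, calibration) {
  if (inherits(models, "ssd_model")) models <- list(models)
  if (length(manual_sd) != length(test_images)) {
    stopf("one manual SD value is required per test image")
  }
  if (anyNA(manual_sd)) {
    stopf("missing manual count for image %s", which(is.na(manual_sd))[1])
  }
  area <- calibration_area(calibration)
  cells <- list()
  for (m in seq_along(models)) {
    model <- models[[m]]
    size <- names(models)[m]
    size <- if (!is.null(size) && nzchar(size)) as.numeric(size) else
      model$n_train
    counts <- count_over_thresholds(test_images, model, c_st_values)
    for (j in seq_along(c_st_values)) {
      met <- regression_metrics(manual_sd, counts[, j] / area)
      cells[[length(cells) + 1L]] <- data.frame(
        size = size, c_st = c_st_values[j], r2 = met$r2, rmse = met$rmse)
    }
  }
  grid <- do.call(rbind, cells)
  class(grid) <- c("evaluation_grid", "data.frame")
  grid
}

#' Select the optimum (training size, confidence threshold) cell
#'
#' Combines the two accuracy criteria: among the cells whose R2 is within
#' `r2_tol` of the grid maximum (differences smaller than the
#' batch-to-batch variability of R2 itself), the cell with the lowest
#' RMSE wins; remaining ties go to the smaller training size and lower
#' threshold. With `r2_tol = 0` this reduces to a pure R2 argmax with
#' RMSE tie-breaking.
#'
#' @param grid an [grid_evaluate()] result.
#' @param r2_tol R2 plateau tolerance (default 0.01).
#' @return the selected row of the grid.
#' @export
select_optimum <- function(grid, r2_tol = 0.01) {
  plateau <- grid[grid$r2 >= max(grid$r2) - r2_tol, , drop = FALSE]
  ord <- order(plateau$rmse, -plateau$r2, plateau$size, plateau$c_st)
  out <- plateau[ord[1], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.evaluation_grid <- function(x, ...) {
  cat(sprintf("Evaluation grid: %d size(s) x %d threshold(s)\n",
              length(unique(x$size)), length(unique(x$c_st))))
  best <- select_optimum(x)
  cat(sprintf("  optimum: size %g, C_st %.2f (R2 = %.3f, RMSE = %.2f)\n",
              best$size, best$c_st, best$r2, best$rmse))
  invisible(x)
}

#' Plot an evaluation grid as R2 / RMSE heat maps
#'
#' @param x an `evaluation_grid`.
#' @param metric `"r2"` or `"rmse"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.evaluation_grid <- function(x, metric = c("r2", "rmse"), ...) {
  metric <- match.arg(metric)
  sizes <- sort(unique(x$size))
  cs <- sort(unique(x$c_st))
  z <- matrix(NA_real_, length(sizes), length(cs))
  for (k in seq_len(nrow(x))) {
    z[match(x$size[k], sizes), match(x$c_st[k], cs)] <- x[[metric]][k]
  }
  graphics::image(seq_along(sizes), seq_along(cs), z, axes = FALSE,
                  xlab = "training images", ylab = "C_st",
                  main = toupper(metric),
                  col = grDevices::gray.colors(64), ...)
  graphics::axis(1, seq_along(sizes), sizes)
  graphics::axis(2, seq_along(cs), cs)
  invisible(z)
}

#' Batch-resampled model comparison with Tukey-Kramer test
#'
#' Draws `n_batches` batches of `batch_size` images from the test pool
#' (without replacement within a batch; independently across batches by
#' default, or as a disjoint partition), computes per-batch R2 and RMSE
#' for every model, and applies the Tukey-Kramer all-pairs comparison to
#' the per-batch metrics across models -- the check that model accuracy
#' differences are (or are not) statistically meaningful.
#'
#' @param models named list of fitted `ssd_model`s, or a precomputed
#'   numeric matrix of automatic SD (images x models).
#' @param c_st confidence threshold applied to every model.
#' @param test_images list of test images (ignored when `models` is a
#'   matrix).
#' @param manual_sd manual SD per test image.
#' @param calibration [calibration_spec()] or area in mm2.
#' @param n_batches,batch_size resampling design (protocol default: 10
#'   batches of 50 images).
#' @param seed RNG seed for the batch draws.
#' @param disjoint if `TRUE` the batches partition the sampled pool.
#' @return a `batch_comparison`: per-batch metric table plus Tukey-Kramer
#'   pair tables for R2 and RMSE.
#' @export
batch_resample_evaluate <- function(models, c_st = 0.3, test_images = NULL,
                                    manual_sd, calibration = NULL,
                                    n_batches = 10L, batch_size = 50L,
                                    seed = 1L, disjoint = FALSE) {
  if (n_batches < 2L) stopf("at least two batches are required")
  if (is.matrix(models)) {
    auto <- models
  } else {
    if (inherits(models, "ssd_model")) models <- list(model = models)
    auto <- vapply(models, function(m)
      measure_sd(test_images, m, c_st, calibration),
      numeric(length(test_images)))
  }
  if (is.null(colnames(auto))) {
    colnames(auto) <- paste0("model", seq_len(ncol(auto)))
  }
  n_pool <- length(manual_sd)
  if (nrow(auto) != n_pool) stopf("auto and manual SD must align")
  if (batch_size > n_pool) stopf("batch_size exceeds the test pool")
  if (disjoint && n_batches * batch_size > n_pool) {
    stopf("disjoint batches need n_batches * batch_size <= pool size")
  }
  batches <- with_seed(seed, {
    if (disjoint) {
      idx <- sample.int(n_pool, n_batches * batch_size)
      split(idx, rep(seq_len(n_batches), each = batch_size))
    } else {
      lapply(seq_len(n_batches), function(b) sample.int(n_pool, batch_size))
    }
  })
  rows <- list()
  for (b in seq_len(n_batches)) {
    for (m in colnames(auto)) {
      met <- regression_metrics(manual_sd[batches[[b]]],
                                auto[batches[[b]], m])
      rows[[length(rows) + 1L]] <- data.frame(
        batch = b, model = m, r2 = met$r2, rmse = met$rmse)
    }
  }
  metrics <- do.call(rbind, rows)
  out <- list(metrics = metrics,
              tukey_r2 = tukey_groups(metrics$r2, metrics$model),
              tukey_rmse = tukey_groups(metrics$rmse, metrics$model),
              n_batches = n_batches, batch_size = batch_size, seed = seed,
              disjoint = disjoint)
  class(out) <- "batch_comparison"
  out
}

#' @export
print.batch_comparison <- function(x, ...) {
  cat(sprintf("Batch comparison: %d batches of %d images, %d model(s)\n",
              x$n_batches, x$batch_size, length(unique(x$metrics$model))))
  agg <- aggregate(cbind(r2, rmse) ~ model, x$metrics, mean)
  print(agg, row.names = FALSE)
  sig <- x$tukey_r2$pairs[x$tukey_r2$pairs$significant, , drop = FALSE]
  cat(sprintf("  Tukey-Kramer on R2: %d of %d pairs significant\n",
              nrow(sig), nrow(x$tukey_r2$pairs)))
  invisible(x)
}
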