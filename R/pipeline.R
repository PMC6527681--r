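# End-to-end workflows: synthesize -> train -> select -> quantify ->
# analyze, with seeded reproducibility and a machine-readable run
# manifest. These are the functions behind the command-line tool.

#' Configuration for the benchmark workflow
#'
#' Defaults follow the phenotyping protocol at desk scale: a 200-image
#' training pool and 150 test images of synthetic replica scenes with true
#' densities spanning the 93--166 mm-2 panel range, 50 training epochs,
#' the 0.10..0.95 confidence-threshold axis, and a pseudo-accession panel
#' with 3 leaflets x 3 positions x 3 images each. Positional offsets
#' (base/middle/tip) emulate the observed tendency for the leaflet tip to
#' carry slightly more stomata.
#'
#' @param seed global seed; every stochastic stage derives from it.
#' @param spec scene specification shared by all stages.
#' @param n_train_pool,train_sizes,epochs,lr,sgd_batch training stage.
#' @param n_test,c_st_values,density_range evaluation stage.
#' @param n_accessions,n_origins,leaflets_per_accession,images_per_position,
#'   position_effects,leaflet_sd panel stage.
#' @param n_batches,batch_size batch-resampling stage (used when more than
#'   one training size is swept).
#' @param bin_width histogram bin width, mm-2.
#' @return a `benchmark_config` list.
#' @export
benchmark_config <- function(seed = 1L, spec = scene_spec(),
                             n_train_pool = 200L,
                             train_sizes = c(25L, 75L, 175L),
                             epochs = 50L, lr = 2e-3, sgd_batch = 8L,
                             n_test = 150L,
                             c_st_values = c_st_axis(),
                             density_range = c(93, 166),
                             n_accessions = 10L, n_origins = 5L,
                             leaflets_per_accession = 3:4,
                             images_per_position = 3L,
                             position_effects = c(base = -1.33,
                                                  middle = -2.33,
                                                  tip = 3.67),
                             leaflet_sd = 3, n_batches = 10L,
                             batch_size = 50L, bin_width = 5) {
  structure(as.list(environment()), class = "benchmark_config")
}

# Deterministic sub-seeds for the pipeline stages, all derived from the
# single global seed (kept well below .Machine$integer.max).
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 101L + stage * 7919L) %% 2000000011L
}

#' Synthesize a pseudo-accession panel and quantify it with a detector
#'
#' Generates the panel scene-by-scene (accession x leaflet x position x
#' image), immediately counts stomata with the supplied model, and
#' discards each raster, so arbitrarily large panels run in constant
#' memory. Accession base densities are evenly spaced over
#' `density_range`; position offsets and a leaflet-level random effect are
#' added, and the Poisson count model supplies image-level noise. A
#' synthetic leaf-area value (uncorrelated with SD) accompanies each
#' leaflet.
#'
#' @param model fitted `ssd_model` (or `NULL` to record truth only).
#' @param c_st confidence threshold used for counting.
#' @param config a [benchmark_config()].
#' @return data frame with one row per image: metadata, `true_count`,
#'   `true_sd`, `la`, and (given a model) `auto_count`, `auto_sd`.
#' @export
quantify_panel <- function(model, c_st, config = benchmark_config()) {
  spec <- config$spec
  area <- scene_area_mm2(spec)
  positions <- names(config$position_effects)
  base_density <- seq(config$density_range[1], config$density_range[2],
                      length.out = config$n_accessions)
  rows <- list()
  with_seed(stage_seed(config$seed, 4L), {
    for (a in seq_len(config$n_accessions)) {
      n_leaflets <- if (length(config$leaflets_per_accession) > 1L) {
        sample(config$leaflets_per_accession, 1L)
      } else config$leaflets_per_accession
      origin <- sprintf("origin_%02d",
                        1L + (a - 1L) %% config$n_origins)
      la_acc <- max(rnorm(1, 18.4, 4.5), 6)
      for (r in seq_len(n_leaflets)) {
        leaf_eff <- rnorm(1, 0, config$leaflet_sd)
        la <- max(rnorm(1, la_acc, 1.5), 5)
        for (p in positions) {
          dens <- max(base_density[a] + config$position_effects[[p]] +
                        leaf_eff, 5)
          for (img in seq_len(config$images_per_position)) {
            s <- spec
            s$true_density <- dens
            s$seed <- NULL
            scene <- generate_scene(s)
            row <- data.frame(accession = sprintf("acc_%02d", a),
                              origin = origin, replicate = r,
                              position = p, image = img,
                              programmed_sd = dens,
                              true_count = scene$truth$count,
                              true_sd = scene$truth$sd, la = la)
            if (!is.null(model)) {
              row$auto_count <- count_stomata(scene, model, c_st)
              row$auto_sd <- row$auto_count / area
            }
            rows[[length(rows) + 1L]] <- row
          }
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full benchmark workflow
#'
#' Emulates the complete phenotyping study on synthetic data: generate a
#' training pool and test set, train the detector at each requested
#' training size, evaluate the training-size x confidence-threshold grid
#' against the test-set truth, select the optimum operating point,
#' quantify a pseudo-accession panel with it, aggregate densities, and
#' run the diversity statistics. All tables and a JSON run manifest are
#' written under `out_dir`; the same config and seed reproduce identical
#' outputs.
#'
#' @param out_dir output directory.
#' @param config a [benchmark_config()].
#' @param verbose print stage progress to stderr.
#' @return a `benchmark_report` list with every stage result.
#' @export
run_benchmark <- function(out_dir, config = benchmark_config(),
                          verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  area <- scene_area_mm2(config$spec)

  say("[1/6] synthesizing training pool (%d) and test set (%d)",
      config$n_train_pool, config$n_test)
  train_pool <- generate_scenes(config$n_train_pool, config$density_range,
                                config$spec,
                                seed = stage_seed(config$seed, 1L))
  test_set <- generate_scenes(config$n_test, config$density_range,
                              config$spec,
                              seed = stage_seed(config$seed, 2L))
  manual_sd <- vapply(test_set, function(s) s$truth$sd, numeric(1))

  say("[2/6] training %d model(s): sizes %s, %d epochs",
      length(config$train_sizes),
      paste(config$train_sizes, collapse = "/"), config$epochs)
  cfg <- ssd_config(input_size = config$spec$image_size)
  models <- list()
  for (sz in config$train_sizes) {
    say("      training size %d", sz)
    models[[as.character(sz)]] <- train_detector(
      train_pool, size = sz, epochs = config$epochs,
      seed = stage_seed(config$seed, 3L), config = cfg, lr = config$lr,
      batch_size = config$sgd_batch)
  }

  say("[3/6] evaluating the size x C_st grid (%d cells)",
      length(models) * length(config$c_st_values))
  grid <- grid_evaluate(models, config$c_st_values, test_set, manual_sd,
                        area)
  optimum <- select_optimum(grid)
  say("      optimum: size %g, C_st %.2f (R2 %.3f, RMSE %.2f)",
      optimum$size, optimum$c_st, optimum$r2, optimum$rmse)
  best_model <- models[[as.character(optimum$size)]]

  batches <- NULL
  if (length(models) > 1L) {
    say("[4/6] batch-resampled model comparison (%d x %d)",
        config$n_batches, config$batch_size)
    batches <- batch_resample_evaluate(
      models, c_st = optimum$c_st, test_images = test_set,
      manual_sd = manual_sd, calibration = area,
      n_batches = config$n_batches,
      batch_size = min(config$batch_size, config$n_test),
      seed = stage_seed(config$seed, 5L))
  } else {
    say("[4/6] single training size; skipping batch comparison")
  }

  say("[5/6] quantifying the %d-accession panel", config$n_accessions)
  panel <- quantify_panel(best_model, optimum$c_st, config)
  records <- density_records(data.frame(
    accession = panel$accession, origin = panel$origin,
    replicate = panel$replicate, position = panel$position,
    sd = panel$auto_sd))
  la_tab <- unique(panel[c("accession", "replicate", "la")])
  names(la_tab)[3] <- "la"
  leaflets <- leaflet_summaries(records, la_tab)
  summary_tabs <- accession_summary(leaflets)

  say("[6/6] diversity statistics")
  anova_sd <- two_way_anova(leaflets_long(leaflets))
  anova_la <- one_way_anova(leaflets$la, leaflets$accession)
  corr <- tryCatch(
    correlation_sd_la(summary_tabs$accessions$sd_all_mean,
                      summary_tabs$accessions$la_mean),
    error = function(e) {
      warning("SD-LA correlation not computable: ", conditionMessage(e))
      list(R = NA_real_, n = nrow(summary_tabs$accessions), t = NA_real_,
           p = NA_real_, signif = "")
    })
  tukey <- tukey_groups(leaflets$sd_all, leaflets$origin)
  hist_tab <- origin_histogram(summary_tabs$accessions$sd_all_mean,
                               summary_tabs$accessions$origin,
                               config$bin_width)

  report <- list(config = config, grid = grid, optimum = optimum,
                 models = models, batches = batches, panel = panel,
                 records = records, leaflets = leaflets,
                 accession_summary = summary_tabs, anova_sd = anova_sd,
                 anova_la = anova_la, correlation = corr, tukey = tukey,
                 histogram = hist_tab)
  class(report) <- "benchmark_report"
  write_benchmark_report(report, out_dir)
  report
}

# replicate-level long table (one row per leaflet x position) feeding the
# two-way ANOVA
leaflets_long <- function(leaflets) {
  long <- rbind(
    data.frame(accession = leaflets$accession, position = "base",
               replicate = leaflets$replicate, sd = leaflets$sd_base),
    data.frame(accession = leaflets$accession, position = "middle",
               replicate = leaflets$replicate, sd = leaflets$sd_middle),
    data.frame(accession = leaflets$accession, position = "tip",
               replicate = leaflets$replicate, sd = leaflets$sd_tip))
  long
}

write_benchmark_report <- function(report, out_dir) {
  wcsv <- function(x, name) write.csv(x, file.path(out_dir, name),
                                      row.names = FALSE)
  wcsv(as.data.frame(report$grid), "grid.csv")
  wcsv(report$optimum, "optimum.csv")
  wcsv(report$panel, "panel_images.csv")
  wcsv(report$records, "density_records.csv")
  wcsv(report$leaflets, "leaflet_summaries.csv")
  wcsv(report$accession_summary$accessions, "accession_summary.csv")
  wcsv(report$accession_summary$panel, "panel_range.csv")
  wcsv(as.data.frame(report$anova_sd), "anova_sd.csv")
  wcsv(as.data.frame(report$anova_la), "anova_la.csv")
  wcsv(report$tukey$pairs, "tukey_origin.csv")
  wcsv(data.frame(bin_mid = report$histogram$mids,
                  report$histogram$counts, check.names = FALSE),
       "histogram.csv")
  if (!is.null(report$batches)) wcsv(report$batches$metrics,
                                     "batch_metrics.csv")
  cfg <- report$config
  cfg$spec <- unclass(cfg$spec)
  manifest <- list(
    package = "stomadet",
    version = as.character(utils::packageVersion("stomadet")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config = unclass(cfg),
    correlation = report$correlation,
    optimum = as.list(report$optimum))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Benchmark report\n")
  cat(sprintf("  optimum: size %g, C_st %.2f, R2 %.3f, RMSE %.2f mm-2\n",
              x$optimum$size, x$optimum$c_st, x$optimum$r2,
              x$optimum$rmse))
  rng <- x$accession_summary$panel
  sd_all <- rng[rng$trait == "sd_all", ]
  cat(sprintf("  panel SD_all range: %.0f to %.0f mm-2 (mean %.0f)\n",
              sd_all$min, sd_all$max, sd_all$mean))
  cat(sprintf("  two-way ANOVA: accession %s, position %s, interaction %s\n",
              x$anova_sd$signif[1], x$anova_sd$signif[2],
              x$anova_sd$signif[3]))
  invisible(x)
}

#' Detect stomata over a directory of micrographs
#'
#' Per-image detection with a fitted model: writes a detections CSV, a
#' counts/density CSV, and overlay PNGs with detection boxes drawn.
#' Unreadable images are skipped with a warning.
#'
#' @param images directory containing PNG/TIFF micrographs, or a character
#'   vector of image paths.
#' @param model fitted `ssd_model` (or path to a [save_model()] file).
#' @param c_st confidence threshold.
#' @param calibration [calibration_spec()] used for density conversion.
#' @param out_dir output directory.
#' @param overlays write overlay PNGs (default TRUE).
#' @return data frame of per-image counts and densities, invisibly.
#' @export
run_detect <- function(images, model, c_st, calibration, out_dir,
                       overlays = TRUE) {
  if (is.character(model)) model <- load_model(model)
  if (length(images) == 1L && dir.exists(images)) {
    images <- list.files(images, pattern = "\\.(png|tif|tiff)$",
                         ignore.case = TRUE, full.names = TRUE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dets <- list(); rows <- list(); skipped <- character(0)
  for (path in images) {
    img <- tryCatch(read_micrograph(path), error = function(e) NULL)
    if (is.null(img)) {
      warning(sprintf("skipping unreadable image: %s", path))
      skipped <- c(skipped, path)
      next
    }
    det <- detect(img, model, c_st)
    if (nrow(det)) {
      det$image_id <- basename(path)
      dets[[length(dets) + 1L]] <- det
    }
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = basename(path), count = nrow(det),
      sd = stomatal_density(nrow(det), calibration))
    if (overlays) {
      write_overlay(img, det,
                    file.path(out_dir, paste0("overlay_", basename(path))))
    }
  }
  det_tab <- if (length(dets)) do.call(rbind, dets) else
    data.frame(xmin = numeric(0), ymin = numeric(0), xmax = numeric(0),
               ymax = numeric(0), score = numeric(0),
               image_id = character(0))
  counts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(0), count = integer(0),
               sd = numeric(0))
  write.csv(det_tab[c("image_id", setdiff(names(det_tab), "image_id"))],
            file.path(out_dir, "detections.csv"), row.names = FALSE)
  write.csv(counts, file.path(out_dir, "densities.csv"), row.names = FALSE)
  if (length(skipped)) {
    message(sprintf("%d image(s) skipped as unreadable", length(skipped)))
  }
  invisible(counts)
}

# Burn detection rectangles into an RGB copy of a grayscale raster.
write_overlay <- function(img, det, path) {
  h <- nrow(img); w <- ncol(img)
  rgb <- array(rep(pmin(pmax(img, 0), 1), 3), dim = c(h, w, 3))
  if (nrow(det)) {
    for (k in seq_len(nrow(det))) {
      x0 <- max(floor(det$xmin[k]) + 1L, 1L)
      x1 <- min(ceiling(det$xmax[k]), w)
      y0 <- max(floor(det$ymin[k]) + 1L, 1L)
      y1 <- min(ceiling(det$ymax[k]), h)
      col <- c(1, 0.6, 0)
      for (ch in 1:3) {
        rgb[y0, x0:x1, ch] <- col[ch]
        rgb[y1, x0:x1, ch] <- col[ch]
        rgb[y0:y1, x0, ch] <- col[ch]
        rgb[y0:y1, x1, ch] <- col[ch]
      }
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}
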