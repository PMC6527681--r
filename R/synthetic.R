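# Synthetic leaf-replica micrographs with exact ground truth.
#
# The generator emulates what a replica micrograph of the abaxial leaf
# surface looks like to a detector: dark elliptical stoma complexes (two
# guard cells flanking a lighter pore slit) scattered at a target density
# over a rugose, low-contrast background that mimics epidermal-cell
# relief, plus sensor noise. Every rendered complex carries a tight
# axis-aligned ground-truth box, so every downstream stage is trainable
# and testable without proprietary image data.

#' Specification of a synthetic replica scene
#'
#' Defaults describe the emulated acquisition: a square raster whose
#' field of view matches a 1840 px native micrograph at 0.5 um/px
#' (0.8464 mm2), rendered at the 300 px detector resolution
#' (3.067 um/px); stoma complexes 20--30 um long and 10--15 um wide with
#' uniformly random orientation, placed by hard-core sampling with a
#' 30 um minimum center spacing (stomata do not touch).
#'
#' @param image_size raster side in pixels.
#' @param um_per_px calibration in micrometers per pixel.
#' @param true_density target stomatal density in stomata per mm2.
#' @param stoma_length_range,stoma_width_range complex length/width in um.
#' @param relief_amplitude background relief standard deviation (intensity
#'   units on the `[0,1]` gray scale).
#' @param relief_corr_um background relief correlation length in um.
#' @param noise_sd additive pixel noise standard deviation.
#' @param min_center_distance hard-core minimum spacing between stoma
#'   centers, in um.
#' @param count_model `"poisson"` (count ~ Poisson(density x area)) or
#'   `"fixed"` (count = round(density x area)).
#' @param base_gray background mean gray level.
#' @param stoma_contrast darkening of the stoma complex below background.
#' @param pore_contrast lightening of the central pore slit.
#' @param seed optional RNG seed; if `NULL` the current RNG stream is used
#'   (so dataset-level seeding stays reproducible).
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(image_size = 300L, um_per_px = 920 / 300,
                       true_density = 130,
                       stoma_length_range = c(20, 30),
                       stoma_width_range = c(10, 15),
                       relief_amplitude = 0.08, relief_corr_um = 20,
                       noise_sd = 0.02, min_center_distance = 30,
                       count_model = c("poisson", "fixed"),
                       base_gray = 0.62, stoma_contrast = 0.35,
                       pore_contrast = 0.18, seed = NULL) {
  count_model <- match.arg(count_model)
  if (um_per_px <= 0) stopf("um_per_px must be positive")
  if (true_density < 0 || noise_sd < 0 || relief_amplitude < 0 ||
      min_center_distance < 0) {
    stopf("densities, noise and spacing must be non-negative")
  }
  structure(list(image_size = as.integer(image_size), um_per_px = um_per_px,
                 true_density = true_density,
                 stoma_length_range = stoma_length_range,
                 stoma_width_range = stoma_width_range,
                 relief_amplitude = relief_amplitude,
                 relief_corr_um = relief_corr_um,
                 noise_sd = noise_sd,
                 min_center_distance = min_center_distance,
                 count_model = count_model, base_gray = base_gray,
                 stoma_contrast = stoma_contrast,
                 pore_contrast = pore_contrast, seed = seed),
            class = "scene_spec")
}

scene_area_mm2 <- function(spec) {
  (spec$um_per_px * spec$image_size * 1e-3)^2
}

# Smooth random relief field: white noise on a coarse grid, bilinearly
# upsampled, in two octaves, standardized to the requested amplitude.
relief_field <- function(size, corr_px, amplitude) {
  if (amplitude <= 0) return(matrix(0, size, size))
  octave <- function(corr) {
    g <- max(2L, as.integer(ceiling(size / max(corr, 1))) + 1L)
    resize_bilinear_cpp(matrix(rnorm(g * g), g, g), size, size)
  }
  f <- octave(corr_px) + 0.5 * octave(corr_px / 2)
  f <- f - mean(f)
  s <- sd(as.numeric(f))
  if (s > 0) f <- f * (amplitude / s)
  f
}

# Hard-core sequential placement with bounded retries.
place_centers <- function(n, size, margin, min_dist_px, retries = 200L) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  xs <- numeric(n); ys <- numeric(n)
  lo <- margin; hi <- size - margin
  if (hi <= lo) stopf("stomata do not fit inside the raster")
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(retries)) {
      x <- runif(1, lo, hi); y <- runif(1, lo, hi)
      if (i == 1L ||
          all((xs[seq_len(i - 1)] - x)^2 + (ys[seq_len(i - 1)] - y)^2 >=
              min_dist_px^2)) {
        xs[i] <- x; ys[i] <- y; ok <- TRUE; break
      }
    }
    if (!ok) {
      stopf("requested density infeasible under the minimum-distance %s",
            "constraint (placement failed after 200 retries)")
    }
  }
  cbind(x = xs, y = ys)
}

#' Generate one synthetic replica scene
#'
#' @param spec a [scene_spec()].
#' @return a `synthetic_scene` (also an [annotated_image()]): grayscale
#'   raster, tight ground-truth boxes, and the truth record
#'   (`true_count`, `true_sd` in mm-2).
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    size <- spec$image_size
    area <- scene_area_mm2(spec)
    lambda <- spec$true_density * area
    n <- switch(spec$count_model,
                fixed = as.integer(round_half_up(lambda)),
                poisson = rpois(1, lambda))
    # per-stoma geometry (pixels)
    len <- runif(n, spec$stoma_length_range[1], spec$stoma_length_range[2])
    wid <- runif(n, spec$stoma_width_range[1], spec$stoma_width_range[2])
    theta <- runif(n, 0, pi)
    a <- len / 2 / spec$um_per_px
    b <- wid / 2 / spec$um_per_px
    ex <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
    ey <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
    margin <- if (n > 0L) max(ex, ey) + 1 else 1
    centers <- place_centers(n, size, margin,
                             spec$min_center_distance / spec$um_per_px)
    img <- spec$base_gray +
      relief_field(size, spec$relief_corr_um / spec$um_per_px,
                   spec$relief_amplitude)
    boxes <- data.frame(xmin = numeric(0), ymin = numeric(0),
                        xmax = numeric(0), ymax = numeric(0),
                        label = character(0))
    for (i in seq_len(n)) {
      cx <- centers[i, 1]; cy <- centers[i, 2]
      x0 <- max(floor(cx - ex[i]), 0); x1 <- min(ceiling(cx + ex[i]), size)
      y0 <- max(floor(cy - ey[i]), 0); y1 <- min(ceiling(cy + ey[i]), size)
      cols <- (x0 + 1):x1          # 1-based raster indices
      rows <- (y0 + 1):y1
      # pixel centers in continuous coordinates
      px <- matrix(cols - 0.5, length(rows), length(cols), byrow = TRUE) - cx
      py <- matrix(rows - 0.5, length(rows), length(cols)) - cy
      u <- px * cos(theta[i]) + py * sin(theta[i])
      v <- -px * sin(theta[i]) + py * cos(theta[i])
      r2 <- (u / a[i])^2 + (v / b[i])^2
      body <- pmin(pmax((1 - r2) / 0.35, 0), 1)      # soft ellipse edge
      pore <- pmin(pmax((1 - (v / (0.35 * b[i]))^2), 0), 1) *
        pmin(pmax((1 - (u / (0.70 * a[i]))^2) / 0.3, 0), 1)
      patch <- img[rows, cols] - spec$stoma_contrast * body +
        spec$pore_contrast * body * pore
      img[rows, cols] <- patch
      boxes[i, c("xmin", "ymin", "xmax", "ymax")] <- c(x0, y0, x1, y1)
      boxes[i, "label"] <- "stoma"
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(size * size, 0, spec$noise_sd), size, size)
    }
    img <- pmin(pmax(img, 0), 1)
    out <- annotated_image(image = img, boxes = boxes,
                           metadata = list(synthetic = TRUE))
    out$truth <- list(count = n, sd = n / area, area_mm2 = area,
                      density = spec$true_density)
    out$spec <- spec
    class(out) <- c("synthetic_scene", class(out))
    out
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "Synthetic replica scene %dx%d px: %d stomata, true SD %.1f mm-2\n",
    x$width, x$height, x$truth$count, x$truth$sd))
  invisible(x)
}

#' Generate a synthetic annotated dataset on disk
#'
#' Draws a per-image density uniformly from `density_range` (defaulting to
#' the 93--166 mm-2 span observed across a diverse soybean panel), renders
#' each scene, and writes PNG rasters, VOC XML annotations, and a manifest
#' CSV carrying the true counts and densities.
#'
#' @param out_dir output directory (created if needed).
#' @param n_images number of scenes.
#' @param density_range range of true densities, mm-2.
#' @param spec template [scene_spec()]; its density and seed are
#'   overridden per image.
#' @param seed RNG seed governing the whole dataset.
#' @return the manifest data frame, invisibly.
#' @export
generate_dataset <- function(out_dir, n_images, density_range = c(93, 166),
                             spec = scene_spec(), seed = 1L) {
  if (!is_count(n_images) || n_images < 1) {
    stopf("n_images must be a positive integer")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n_images)
  with_seed(seed, {
    for (i in seq_len(n_images)) {
      s <- spec
      s$true_density <- runif(1, density_range[1], density_range[2])
      s$seed <- NULL
      scene <- generate_scene(s)
      img_path <- file.path(out_dir, sprintf("scene_%04d.png", i))
      xml_path <- file.path(out_dir, sprintf("scene_%04d.xml", i))
      scene$image_path <- basename(img_path)
      write_micrograph(scene$image, img_path)
      write_voc_annotation(scene, xml_path)
      rows[[i]] <- data.frame(path = img_path, xml = xml_path,
                              true_count = scene$truth$count,
                              true_sd = scene$truth$sd)
    }
  })
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}

#' Generate a list of in-memory scenes
#'
#' Convenience used by the training and evaluation harnesses: like
#' [generate_dataset()] but without touching disk.
#'
#' @inheritParams generate_dataset
#' @return list of `synthetic_scene` objects.
#' @export
generate_scenes <- function(n_images, density_range = c(93, 166),
                            spec = scene_spec(), seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n_images), function(i) {
      s <- spec
      s$true_density <- runif(1, density_range[1], density_range[2])
      s$seed <- NULL
      generate_scene(s)
    })
  })
}
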