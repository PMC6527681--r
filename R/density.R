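# Count -> density conversion and the positional / leaflet / accession
# aggregation of stomatal density.
#
# Counting is invariant to the detector's input resize, so densities are
# always referred back to the native imaged area through an explicit
# calibration (the microscope magnification alone does not fix the
# field-of-view area, hence calibration is a required input everywhere).

#' Imaging calibration
#'
#' @param um_per_px micrometers per pixel at the native resolution.
#' @param width_px,height_px native raster extent in pixels (default the
#'   1840 x 1840 acquisition format).
#' @return a `calibration_spec` with the derived imaged area in mm2.
#' @export
calibration_spec <- function(um_per_px = 0.5, width_px = 1840L,
                             height_px = width_px) {
  if (um_per_px <= 0 || width_px <= 0 || height_px <= 0) {
    stopf("calibration requires positive um_per_px and extent")
  }
  area <- (um_per_px * width_px * 1e-3) * (um_per_px * height_px * 1e-3)
  structure(list(um_per_px = um_per_px, width_px = as.integer(width_px),
                 height_px = as.integer(height_px), area_mm2 = area),
            class = "calibration_spec")
}

calibration_area <- function(calibration) {
  area <- if (inherits(calibration, "calibration_spec")) {
    calibration$area_mm2
  } else if (inherits(calibration, "scene_spec")) {
    scene_area_mm2(calibration)
  } else if (is.numeric(calibration) && length(calibration) == 1L) {
    calibration
  } else {
    stopf("calibration must be a calibration_spec or an area in mm2")
  }
  if (is.na(area) || area <= 0) stopf("imaged area must be positive")
  area
}

#' Stomatal density of one image
#'
#' SD = count / imaged area, in stomata per mm2.
#'
#' @param count non-negative stomata count(s).
#' @param calibration a [calibration_spec()] (or an area in mm2).
#' @return SD in mm-2 (vectorized over `count`).
#' @export
stomatal_density <- function(count, calibration) {
  if (any(count < 0)) stopf("counts must be non-negative")
  count / calibration_area(calibration)
}

#' Positional mean density
#'
#' Averages the SD of the (typically three) micrographs taken at one
#' position of one leaflet replica into a single positional record.
#'
#' @param image_densities numeric vector of per-image SD (mm-2).
#' @return list with `sd` (mean) and `n_images`.
#' @export
position_density <- function(image_densities) {
  n <- length(image_densities)
  if (n == 0L) stopf("no image densities supplied for this position")
  if (n > 3L) warning("more than 3 images per position; protocol uses 3")
  list(sd = mean(image_densities), n_images = n)
}

#' Summarize one leaflet
#'
#' Combines the three positional means into the leaflet record:
#' `sd_all` is the unweighted mean of `sd_base`, `sd_middle`, `sd_tip`
#' (two-stage averaging: images -> position -> leaflet).
#'
#' @param records_for_leaflet data frame with columns `position`
#'   (base/middle/tip) and `sd` for one leaflet.
#' @param leaf_area leaflet blade area in cm2 (external measurement),
#'   optional.
#' @return one-row data frame with `sd_base`, `sd_middle`, `sd_tip`,
#'   `sd_all`, `la`.
#' @export
leaflet_summary <- function(records_for_leaflet, leaf_area = NA_real_) {
  need <- c("base", "middle", "tip")
  got <- records_for_leaflet$position
  missing <- setdiff(need, got)
  if (length(missing)) {
    stopf("missing position(s) for leaflet: %s",
          paste(missing, collapse = ", "))
  }
  pick <- function(p) records_for_leaflet$sd[match(p, got)]
  sd_pos <- vapply(need, pick, numeric(1))
  data.frame(sd_base = sd_pos[1], sd_middle = sd_pos[2], sd_tip = sd_pos[3],
             sd_all = mean(sd_pos), la = leaf_area)
}

#' Image-level table -> positional density records
#'
#' Tidy-table form of [position_density()]: aggregates per-image SD by
#' accession x replicate (leaflet) x position.
#'
#' @param df data frame with columns `accession`, `replicate`, `position`,
#'   and either `sd` or `count`; optional `origin`.
#' @param calibration needed when only `count` is present.
#' @return data frame of density records with `sd` and `n_images`.
#' @export
density_records <- function(df, calibration = NULL) {
  if (is.null(df$sd)) {
    if (is.null(df$count)) stopf("need an sd or count column")
    df$sd <- stomatal_density(df$count, calibration)
  }
  keys <- c("accession", "replicate", "position",
            intersect("origin", names(df)))
  agg <- aggregate(df$sd, df[keys], function(v) c(mean(v), length(v)))
  out <- agg[keys]
  out$sd <- agg$x[, 1]
  out$n_images <- as.integer(agg$x[, 2])
  out[order(out$accession, out$replicate, out$position), , drop = FALSE]
}

#' Positional records -> per-leaflet summaries
#'
#' @param records output of [density_records()].
#' @param leaf_area optional data frame with `accession`, `replicate`
#'   (optional) and `la` (cm2).
#' @return data frame with one row per accession x replicate.
#' @export
leaflet_summaries <- function(records, leaf_area = NULL) {
  keys <- unique(records[c("accession", "replicate",
                           intersect("origin", names(records)))])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- records[records$accession == keys$accession[i] &
                     records$replicate == keys$replicate[i], , drop = FALSE]
    la <- NA_real_
    if (!is.null(leaf_area)) {
      m <- leaf_area$accession == keys$accession[i]
      if (!is.null(leaf_area$replicate)) {
        m <- m & leaf_area$replicate == keys$replicate[i]
      }
      if (any(m)) la <- leaf_area$la[which(m)[1]]
    }
    cbind(keys[i, , drop = FALSE], leaflet_summary(sub, la))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-accession means and standard errors
#'
#' Summarizes leaflet records into the panel table: per accession, mean
#' and standard error (sd / sqrt(n)) of `sd_base`, `sd_middle`, `sd_tip`,
#' `sd_all` and leaf area, plus panel-wide min / max / mean rows over the
#' accession means. With a single leaflet the SE is reported as `NA`.
#'
#' @param leaflets output of [leaflet_summaries()].
#' @return list with `accessions` (per-accession table) and `panel`
#'   (min/max/mean of the accession means, per trait).
#' @export
accession_summary <- function(leaflets) {
  traits <- intersect(c("sd_base", "sd_middle", "sd_tip", "sd_all", "la"),
                      names(leaflets))
  se <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) NA_real_ else sd(v) / sqrt(length(v))
  }
  accs <- unique(leaflets$accession)
  per <- lapply(accs, function(a) {
    sub <- leaflets[leaflets$accession == a, , drop = FALSE]
    row <- data.frame(accession = a, n = nrow(sub))
    if (!is.null(sub$origin)) row$origin <- sub$origin[1]
    for (tr in traits) {
      row[[paste0(tr, "_mean")]] <- mean(sub[[tr]])
      row[[paste0(tr, "_se")]] <- se(sub[[tr]])
    }
    row
  })
  per <- do.call(rbind, per)
  panel <- do.call(rbind, lapply(traits, function(tr) {
    m <- per[[paste0(tr, "_mean")]]
    m <- m[!is.na(m)]
    if (length(m) == 0L) {
      return(data.frame(trait = tr, min = NA_real_, max = NA_real_,
                        mean = NA_real_))
    }
    data.frame(trait = tr, min = min(m), max = max(m), mean = mean(m))
  }))
  list(accessions = per, panel = panel)
}
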