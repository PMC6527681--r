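# Prior (default) boxes: the fixed lattice of reference boxes relative to
# which the detector predicts class scores and coordinate offsets, plus the
# ground-truth matching and the center-size offset encoding.

#' Prior-box lattice configuration
#'
#' One entry per feature map. Each cell of a `grid x grid` map carries one
#' prior per aspect ratio at the given scale (a fraction of the image
#' side): width = scale * sqrt(ratio), height = scale / sqrt(ratio).
#' The defaults put a fine 38x38 map and a coarser 19x19 map over scales
#' spanning the expected stoma box size (roughly 3--5% of the image side).
#'
#' @param grids integer vector of feature-map grid sizes.
#' @param scales numeric vector, same length, of prior scales in (0, 1].
#' @param ratios aspect ratios applied at every cell.
#' @param variances encoding variances `(v_center, v_size)` used by
#'   [encode_boxes()].
#' @return a `prior_config` list.
#' @export
prior_config <- function(grids = c(38L, 19L), scales = c(0.03, 0.05),
                         ratios = c(1, 2, 0.5), variances = c(0.1, 0.2)) {
  if (length(grids) < 1L) stopf("at least one feature map is required")
  if (length(grids) != length(scales)) stopf("grids and scales must align")
  if (length(ratios) < 1L) stopf("at least one aspect ratio is required")
  if (any(scales <= 0 | scales > 1)) stopf("scales must lie in (0, 1]")
  structure(list(grids = as.integer(grids), scales = as.numeric(scales),
                 ratios = as.numeric(ratios),
                 variances = as.numeric(variances)),
            class = "prior_config")
}

#' Generate the prior-box set
#'
#' Lays one prior per (cell, ratio) on each configured feature map,
#' centered on cell centers, and clips every box to the unit square. The
#' ordering is (map, ratio, cell) with the cell row index fastest, which is
#' exactly the ordering of the network head outputs.
#'
#' @param config a [prior_config()].
#' @return a `prior_box_set`: list with `centers` and `corners` (P x 4
#'   matrices in `[0,1]` fractions), the per-map layout, and the variances.
#' @export
generate_priors <- function(config = prior_config()) {
  centers <- NULL
  layout <- list()
  for (m in seq_along(config$grids)) {
    g <- config$grids[m]
    s <- config$scales[m]
    cell <- expand.grid(i = seq_len(g) - 1L, j = seq_len(g) - 1L)
    cy <- (cell$i + 0.5) / g
    cx <- (cell$j + 0.5) / g
    for (r in config$ratios) {
      w <- s * sqrt(r)
      h <- s / sqrt(r)
      centers <- rbind(centers, cbind(cx, cy, rep(w, length(cx)),
                                      rep(h, length(cy))))
    }
    layout[[m]] <- list(grid = g, scale = s, n = g * g * length(config$ratios))
  }
  corners <- cbind(centers[, 1] - centers[, 3] / 2,
                   centers[, 2] - centers[, 4] / 2,
                   centers[, 1] + centers[, 3] / 2,
                   centers[, 2] + centers[, 4] / 2)
  corners <- pmin(pmax(corners, 0), 1)
  dim(corners) <- c(nrow(centers), 4L)
  # re-derive center form from the clipped corners so that encoding and
  # decoding always refer to the same geometry
  centers <- cbind((corners[, 1] + corners[, 3]) / 2,
                   (corners[, 2] + corners[, 4]) / 2,
                   corners[, 3] - corners[, 1],
                   corners[, 4] - corners[, 2])
  colnames(centers) <- c("cx", "cy", "w", "h")
  colnames(corners) <- c("xmin", "ymin", "xmax", "ymax")
  structure(list(centers = centers, corners = corners, layout = layout,
                 config = config, variances = config$variances),
            class = "prior_box_set")
}

#' @export
print.prior_box_set <- function(x, ...) {
  cat("Prior box set:", nrow(x$centers), "priors on",
      length(x$layout), "feature map(s)\n")
  for (m in x$layout) {
    cat(sprintf("  %dx%d grid, scale %.3f, %d priors\n",
                m$grid, m$grid, m$scale, m$n))
  }
  invisible(x)
}

corners_to_centers <- function(corners) {
  cbind(cx = (corners[, 1] + corners[, 3]) / 2,
        cy = (corners[, 2] + corners[, 4]) / 2,
        w = corners[, 3] - corners[, 1],
        h = corners[, 4] - corners[, 2])
}

centers_to_corners <- function(centers) {
  cbind(xmin = centers[, 1] - centers[, 3] / 2,
        ymin = centers[, 2] - centers[, 4] / 2,
        xmax = centers[, 1] + centers[, 3] / 2,
        ymax = centers[, 2] + centers[, 4] / 2)
}

#' Match priors to ground-truth boxes
#'
#' Two-stage assignment used to build training targets: first, every ground
#' truth is force-matched to its best-IoU prior (even below the threshold,
#' so no annotated stoma is ever unsupervised); second, every remaining
#' prior whose IoU with some ground truth reaches `iou_threshold` is
#' assigned to its best ground truth. All other priors are background.
#'
#' @param gt_boxes ground-truth box table in `[0,1]` fractions (may have
#'   zero rows, in which case everything is background).
#' @param priors a `prior_box_set`.
#' @param iou_threshold positive-match threshold (default 0.5).
#' @return a `match_result`: `assignment` (integer per prior, 0 =
#'   background, otherwise ground-truth row index) and `targets` (encoded
#'   offsets for the positive priors, see [encode_boxes()]).
#' @export
match_priors <- function(gt_boxes, priors, iou_threshold = 0.5) {
  n_priors <- nrow(priors$corners)
  if (n_priors == 0L) stopf("prior set is empty")
  assignment <- integer(n_priors)
  if (is.null(gt_boxes) || nrow(gt_boxes) == 0L) {
    return(structure(list(assignment = assignment,
                          targets = matrix(0, 0, 4),
                          positive = integer(0)),
                     class = "match_result"))
  }
  gm <- box_matrix(gt_boxes)
  ov <- iou_matrix(priors$corners, gm)          # priors x gts
  # stage 2 first: threshold matches to each prior's best ground truth
  best_gt <- max.col(ov, ties.method = "first")
  best_ov <- ov[cbind(seq_len(n_priors), best_gt)]
  assignment[best_ov >= iou_threshold] <- best_gt[best_ov >= iou_threshold]
  # stage 1 overrides: each ground truth claims its single best prior
  for (g in seq_len(nrow(gm))) {
    p <- which.max(ov[, g])
    assignment[p] <- g
  }
  positive <- which(assignment > 0L)
  targets <- encode_boxes(gm[assignment[positive], , drop = FALSE],
                          priors$centers[positive, , drop = FALSE],
                          priors$variances)
  structure(list(assignment = assignment, targets = targets,
                 positive = positive),
            class = "match_result")
}

#' Encode ground-truth boxes as prior-relative offsets
#'
#' The center-size parameterization regressed by the detector:
#' `((g_cx - p_cx)/p_w/v_c, (g_cy - p_cy)/p_h/v_c, log(g_w/p_w)/v_s,
#' log(g_h/p_h)/v_s)` with variances `(v_c, v_s)`. [decode_boxes()] is the
#' exact inverse.
#'
#' @param gt_boxes ground-truth boxes in corner form (rows).
#' @param prior_centers matching priors in center form `(cx, cy, w, h)`.
#' @param variances encoding variances `(v_center, v_size)`.
#' @return an `n x 4` matrix of offsets.
#' @export
encode_boxes <- function(gt_boxes, prior_centers, variances = c(0.1, 0.2)) {
  gm <- box_matrix(gt_boxes)
  if (nrow(gm) == 0L) return(matrix(0, 0, 4))
  gc <- corners_to_centers(gm)
  if (any(gc[, 3] <= 0) || any(gc[, 4] <= 0)) {
    stopf("ground-truth box with non-positive width/height cannot be encoded")
  }
  pc <- rbind(prior_centers)
  cbind((gc[, 1] - pc[, 1]) / pc[, 3] / variances[1],
        (gc[, 2] - pc[, 2]) / pc[, 4] / variances[1],
        log(gc[, 3] / pc[, 3]) / variances[2],
        log(gc[, 4] / pc[, 4]) / variances[2])
}

#' Decode prior-relative offsets back into boxes
#'
#' @param offsets an `n x 4` matrix as produced by the network (or by
#'   [encode_boxes()]).
#' @param prior_centers matching priors in center form.
#' @param variances encoding variances `(v_center, v_size)`.
#' @return an `n x 4` matrix of corner-form boxes.
#' @export
decode_boxes <- function(offsets, prior_centers, variances = c(0.1, 0.2)) {
  om <- rbind(offsets)
  pc <- rbind(prior_centers)
  cx <- om[, 1] * variances[1] * pc[, 3] + pc[, 1]
  cy <- om[, 2] * variances[1] * pc[, 4] + pc[, 2]
  w <- exp(om[, 3] * variances[2]) * pc[, 3]
  h <- exp(om[, 4] * variances[2]) * pc[, 4]
  centers_to_corners(cbind(cx, cy, w, h))
}
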