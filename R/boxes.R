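# Axis-aligned bounding-box geometry. Boxes are rows of a numeric matrix or
# data frame with columns xmin, ymin, xmax, ymax (and optionally score).
# Coordinates are half-open intervals [xmin, xmax) x [ymin, ymax): in pixel
# units areas are exact integers, and dividing by the image side maps the
# same boxes onto the detector's canonical [0,1] fractions.

#' Construct a bounding-box table
#'
#' @param xmin,ymin,xmax,ymax numeric vectors of box corners (half-open
#'   convention: the box covers `[xmin, xmax) x [ymin, ymax)`).
#' @param score optional detection confidence in `[0,1]`.
#' @param label optional class label, recycled.
#' @return a data frame with one row per box.
#' @export
bounding_boxes <- function(xmin, ymin, xmax, ymax, score = NULL, label = NULL) {
  df <- data.frame(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
                   xmax = as.numeric(xmax), ymax = as.numeric(ymax))
  if (any(df$xmin >= df$xmax) || any(df$ymin >= df$ymax)) {
    stopf("degenerate box: xmin < xmax and ymin < ymax are required")
  }
  if (!is.null(score)) df$score <- as.numeric(score)
  if (!is.null(label)) df$label <- as.character(label)
  df
}

box_matrix <- function(boxes) {
  if (is.data.frame(boxes)) {
    as.matrix(boxes[, c("xmin", "ymin", "xmax", "ymax")])
  } else {
    m <- as.matrix(boxes)
    if (is.null(dim(m)) || ncol(m) < 4L) stopf("boxes need 4 coordinate columns")
    m[, 1:4, drop = FALSE]
  }
}

box_area <- function(boxes) {
  m <- box_matrix(boxes)
  pmax(m[, 3] - m[, 1], 0) * pmax(m[, 4] - m[, 2], 0)
}

#' Intersection over union of two boxes
#'
#' The overlap ratio used both for matching priors to ground truth and for
#' non-maximum suppression. Degenerate (zero-area) boxes give 0.
#'
#' @param box_a,box_b boxes as length-4 vectors `(xmin, ymin, xmax, ymax)`
#'   or single-row box tables.
#' @return the IoU ratio in `[0, 1]`.
#' @export
iou <- function(box_a, box_b) {
  a <- as.numeric(box_matrix(rbind(as.numeric(box_a)[1:4])))
  b <- as.numeric(box_matrix(rbind(as.numeric(box_b)[1:4])))
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  area_a <- max(a[3] - a[1], 0) * max(a[4] - a[2], 0)
  area_b <- max(b[3] - b[1], 0) * max(b[4] - b[2], 0)
  union <- area_a + area_b - inter
  if (union <= 0) return(0)
  inter / union
}

#' Pairwise IoU matrix
#'
#' @param boxes_a,boxes_b box tables with `n_a` and `n_b` rows.
#' @return an `n_a x n_b` matrix of IoU ratios.
#' @export
iou_matrix <- function(boxes_a, boxes_b) {
  a <- box_matrix(boxes_a); b <- box_matrix(boxes_b)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) return(matrix(0, na, nb))
  ix1 <- pmax(matrix(a[, 1], na, nb), matrix(b[, 1], na, nb, byrow = TRUE))
  iy1 <- pmax(matrix(a[, 2], na, nb), matrix(b[, 2], na, nb, byrow = TRUE))
  ix2 <- pmin(matrix(a[, 3], na, nb), matrix(b[, 3], na, nb, byrow = TRUE))
  iy2 <- pmin(matrix(a[, 4], na, nb), matrix(b[, 4], na, nb, byrow = TRUE))
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  union <- matrix(box_area(a), na, nb) +
    matrix(box_area(b), na, nb, byrow = TRUE) - inter
  out <- ifelse(union > 0, inter / union, 0)
  out
}

#' Greedy non-maximum suppression
#'
#' Keeps the highest-scoring box, suppresses every remaining box whose IoU
#' with a kept box exceeds `nms_iou_threshold`, and repeats until `top_k`
#' boxes are retained. Score ties are broken by lower input row index, so
#' the result is fully deterministic.
#'
#' @param boxes box table with a `score` column.
#' @param nms_iou_threshold overlap above which a lower-scoring box is
#'   suppressed (default 0.45).
#' @param top_k maximum number of boxes retained (default 200).
#' @return the retained rows of `boxes`, highest score first.
#' @export
nms <- function(boxes, nms_iou_threshold = 0.45, top_k = 200L) {
  if (is.null(boxes) || nrow(boxes) == 0L) return(boxes)
  if (is.null(boxes$score)) stopf("nms() requires a score column")
  ord <- order(-boxes$score, seq_len(nrow(boxes)))
  keep <- integer(0)
  m <- box_matrix(boxes)
  while (length(ord) > 0L && length(keep) < top_k) {
    i <- ord[1]
    keep <- c(keep, i)
    ord <- ord[-1]
    if (length(ord) > 0L) {
      ov <- iou_matrix(m[i, , drop = FALSE], m[ord, , drop = FALSE])[1, ]
      ord <- ord[ov <= nms_iou_threshold]
    }
  }
  boxes[keep, , drop = FALSE]
}

#' Filter detections by confidence threshold
#'
#' Retains exactly the detections whose score is strictly greater than the
#' confidence threshold `c_st` (a detection scoring exactly `c_st` is
#' dropped). Raising `c_st` therefore always yields a subset.
#'
#' @param detections box table with a `score` column.
#' @param c_st confidence threshold, strictly between 0 and 1.
#' @return the retained rows.
#' @export
filter_by_confidence <- function(detections, c_st) {
  if (!is.numeric(c_st) || length(c_st) != 1L || c_st <= 0 || c_st >= 1) {
    stopf("c_st must be a single value in (0, 1)")
  }
  if (is.null(detections) || nrow(detections) == 0L) return(detections)
  if (is.null(detections$score)) stopf("detections need a score column")
  detections[detections$score > c_st, , drop = FALSE]
}
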