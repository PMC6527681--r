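# Independent brute-force references used to check the geometry and
# statistics implementations. These deliberately use the most literal
# formulation available (pixel enumeration, explicit loops, textbook
# sums of squares) and share no code with the package internals.

# IoU of two integer pixel boxes by enumerating the pixel grid.
oracle_iou_pixels <- function(a, b) {
  lim <- max(a, b)
  grid_a <- matrix(FALSE, lim, lim)
  grid_b <- matrix(FALSE, lim, lim)
  if (a[3] > a[1] && a[4] > a[2]) {
    grid_a[(a[2] + 1):a[4], (a[1] + 1):a[3]] <- TRUE
  }
  if (b[3] > b[1] && b[4] > b[2]) {
    grid_b[(b[2] + 1):b[4], (b[1] + 1):b[3]] <- TRUE
  }
  inter <- sum(grid_a & grid_b)
  uni <- sum(grid_a | grid_b)
  if (uni == 0) 0 else inter / uni
}

# Continuous-coordinate IoU by direct interval arithmetic.
oracle_iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  uni <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (uni <= 0) 0 else inter / uni
}

# Exhaustive greedy NMS reference: repeated scans, no vectorization.
oracle_nms <- function(boxes, thr, top_k = Inf) {
  keep <- integer(0)
  alive <- seq_len(nrow(boxes))
  while (length(alive) > 0 && length(keep) < top_k) {
    best <- alive[1]
    for (i in alive) if (boxes$score[i] > boxes$score[best]) best <- i
    keep <- c(keep, best)
    alive <- setdiff(alive, best)
    drop <- c()
    for (i in alive) {
      o <- oracle_iou(as.numeric(boxes[best, 1:4]),
                      as.numeric(boxes[i, 1:4]))
      if (o > thr) drop <- c(drop, i)
    }
    alive <- setdiff(alive, drop)
  }
  keep
}

# Exhaustive matching reference: loops over every ground truth x prior
# IoU, applies the threshold rule, then the forced best-prior rule.
oracle_match <- function(gt, priors_corners, thr) {
  np <- nrow(priors_corners)
  ng <- nrow(gt)
  ov <- matrix(0, np, ng)
  for (p in seq_len(np)) for (g in seq_len(ng)) {
    ov[p, g] <- oracle_iou(priors_corners[p, ], gt[g, ])
  }
  assign <- integer(np)
  for (p in seq_len(np)) {
    g <- which.max(ov[p, ])
    if (ov[p, g] >= thr) assign[p] <- g
  }
  for (g in seq_len(ng)) {
    assign[which.max(ov[, g])] <- g
  }
  assign
}

# Balanced factorial sums of squares by direct mean decomposition.
oracle_two_way_ss <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  gm <- mean(y)
  ss_a <- sum(tapply(y, a, function(v) length(v) * (mean(v) - gm)^2))
  ss_b <- sum(tapply(y, b, function(v) length(v) * (mean(v) - gm)^2))
  cell_means <- tapply(y, list(a, b), mean)
  n_cell <- table(a, b)
  ss_cells <- sum(n_cell * (cell_means - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_res <- sum((y - cell_means[cbind(a, b)])^2)
  c(a = ss_a, b = ss_b, ab = ss_ab, residual = ss_res)
}

oracle_one_way_ss <- function(y, g) {
  g <- factor(g)
  gm <- mean(y)
  ss_g <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ss_res <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  c(group = ss_g, residual = ss_res)
}

# Random valid box in [0, lim) with integer corners.
random_pixel_box <- function(lim = 20L) {
  x <- sort(sample.int(lim + 1L, 2L) - 1L)
  while (x[1] == x[2]) x <- sort(sample.int(lim + 1L, 2L) - 1L)
  y <- sort(sample.int(lim + 1L, 2L) - 1L)
  while (y[1] == y[2]) y <- sort(sample.int(lim + 1L, 2L) - 1L)
  c(x[1], y[1], x[2], y[2])
}

# Random valid box in [0,1] fractions.
random_unit_box <- function(min_side = 0.02) {
  repeat {
    v <- sort(runif(2)); w <- sort(runif(2))
    if (v[2] - v[1] >= min_side && w[2] - w[1] >= min_side) {
      return(c(v[1], w[1], v[2], w[2]))
    }
  }
}
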