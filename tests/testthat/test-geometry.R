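# Detection geometry: IoU, prior lattice, matching, encode/decode, NMS,
# confidence filtering.

test_that("iou matches hand values and the pixel-enumeration oracle", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(2, 2, 3, 3)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  # degenerate box
  expect_equal(iou(c(0, 0, 0, 2), c(0, 0, 2, 2)), 0)
  set.seed(11)
  for (k in 1:200) {
    a <- random_pixel_box(15L)
    b <- random_pixel_box(15L)
    expect_equal(iou(a, b), oracle_iou_pixels(a, b))
    expect_equal(iou(a, b), iou(b, a))
  }
})

test_that("iou_matrix agrees with scalar iou", {
  set.seed(3)
  A <- t(replicate(6, random_unit_box()))
  B <- t(replicate(4, random_unit_box()))
  M <- iou_matrix(A, B)
  for (i in 1:6) for (j in 1:4) {
    expect_equal(M[i, j], iou(A[i, ], B[j, ]))
  }
})

test_that("prior lattice has one prior per cell x ratio, clipped to [0,1]", {
  p <- generate_priors(prior_config(grids = 3L, scales = 0.2, ratios = 1))
  expect_equal(nrow(p$centers), 9L)
  p2 <- generate_priors(prior_config(grids = 2L, scales = 0.3,
                                     ratios = c(1, 2)))
  expect_equal(nrow(p2$centers), 8L)
  # large scale at an edge cell must be clipped inside the unit square
  p3 <- generate_priors(prior_config(grids = 2L, scales = 0.9, ratios = 1))
  expect_true(all(p3$corners >= 0 & p3$corners <= 1))
  expect_error(prior_config(grids = 2L, scales = 0.3, ratios = numeric(0)),
               "ratio")
})

test_that("matching forces a positive prior for every ground truth", {
  priors <- generate_priors(prior_config(grids = 4L, scales = 0.25))
  # no ground truth: everything background
  m0 <- match_priors(NULL, priors)
  expect_true(all(m0$assignment == 0L))
  # a tiny box whose best IoU is far below threshold is still matched
  gt <- rbind(c(0.40, 0.40, 0.44, 0.44))
  m1 <- match_priors(gt, priors, iou_threshold = 0.5)
  expect_gte(sum(m1$assignment == 1L), 1L)
  best <- which.max(iou_matrix(priors$corners, gt)[, 1])
  expect_equal(m1$assignment[best], 1L)
})

test_that("matching equals the exhaustive argmax oracle on random scenes", {
  priors <- generate_priors(prior_config(grids = 4L, scales = 0.22,
                                         ratios = c(1, 2, 0.5)))
  set.seed(29)
  for (rep in 1:20) {
    gt <- t(replicate(5, random_unit_box(min_side = 0.05)))
    got <- match_priors(gt, priors, iou_threshold = 0.5)$assignment
    want <- oracle_match(gt, priors$corners, 0.5)
    expect_equal(got, want)
  }
})

test_that("offset encoding matches the stated formula and inverts exactly", {
  # gt == prior: zero offsets
  prior <- cbind(0.5, 0.5, 0.2, 0.2)
  gt_eq <- rbind(c(0.4, 0.4, 0.6, 0.6))
  expect_equal(as.numeric(encode_boxes(gt_eq, prior)), rep(0, 4))
  # shifted center: (0.05 / 0.2) / 0.1 = 2.5 on the x offset
  gt_sh <- rbind(c(0.45, 0.4, 0.65, 0.6))
  expect_equal(as.numeric(encode_boxes(gt_sh, prior)), c(2.5, 0, 0, 0))
  # degenerate ground truth is an error
  expect_error(encode_boxes(rbind(c(0.5, 0.5, 0.5, 0.6)), prior),
               "degenerate|non-positive")
  # inverse property over random pairs
  set.seed(7)
  for (k in 1:500) {
    b <- rbind(random_unit_box())
    p <- rbind(random_unit_box())
    pc <- cbind((p[1] + p[3]) / 2, (p[2] + p[4]) / 2,
                p[3] - p[1], p[4] - p[2])
    dec <- decode_boxes(encode_boxes(b, pc), pc)
    expect_lt(max(abs(dec - b)), 1e-9)
  }
})

test_that("nms keeps the greedy-suppression set, ties broken by index", {
  one <- bounding_boxes(0, 0, 1, 1, score = 0.7)
  expect_equal(nrow(nms(one, 0.45)), 1L)
  two <- bounding_boxes(c(0, 0), c(0, 0), c(1, 1), c(1, 1),
                        score = c(0.9, 0.8))
  expect_equal(nms(two, 0.45)$score, 0.9)
  # equal scores: lower input index wins
  tie <- bounding_boxes(c(0, 0), c(0, 0), c(1, 1), c(1, 1),
                        score = c(0.8, 0.8))
  expect_equal(rownames(nms(tie, 0.45)), "1")
  set.seed(17)
  for (rep in 1:50) {
    n <- sample(2:20, 1)
    boxes <- as.data.frame(t(replicate(n, random_unit_box(0.05))))
    names(boxes) <- c("xmin", "ymin", "xmax", "ymax")
    boxes$score <- round(runif(n), 2)   # rounded scores exercise ties
    thr <- runif(1, 0.2, 0.6)
    got <- nms(boxes, thr)
    want <- boxes[oracle_nms(boxes, thr), , drop = FALSE]
    expect_equal(got, want)
  }
})

test_that("confidence filtering is strict and monotone", {
  det <- bounding_boxes(c(0, 2, 4), c(0, 0, 0), c(1, 3, 5), c(1, 1, 1),
                        score = c(0.2, 0.5, 0.9))
  expect_equal(nrow(filter_by_confidence(det, 0.45)), 2L)
  # a score exactly at the threshold is excluded
  expect_equal(nrow(filter_by_confidence(det, 0.5)), 1L)
  # the protocol requires a strictly positive threshold
  expect_error(filter_by_confidence(det, 0), "0, 1")
  # monotone nesting
  f1 <- filter_by_confidence(det, 0.3)
  f2 <- filter_by_confidence(det, 0.6)
  expect_true(all(rownames(f2) %in% rownames(f1)))
})
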