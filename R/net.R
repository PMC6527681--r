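# Desk-scale convolutional backbone for the single-shot detector.
#
# The network is a stack of 3x3 stride-2 convolutions with ReLU (each
# halving the spatial resolution), with linear 3x3 detection heads attached
# to the later feature maps. Every head cell emits, per aspect ratio, two
# class logits (background, stoma) and four prior-relative box offsets.
# Convolutions run as im2col (C++) + BLAS matrix products; gradients are
# hand-derived, and optimization is Adam. All sources of randomness come
# from R's RNG, so a seed fixes the full training trajectory.

conv_out_size <- function(n, k = 3L, stride = 2L, pad = 1L) {
  as.integer(floor((n + 2L * pad - k) / stride) + 1L)
}

#' Detector architecture and post-processing configuration
#'
#' @param input_size detector input side in pixels (square raster; default
#'   300, the standard single-shot input resolution).
#' @param base_channels output channels of the successive stride-2 backbone
#'   convolutions; the spatial size halves at each.
#' @param head_layers indices of backbone layers whose feature maps carry
#'   detection heads.
#' @param scales prior scale (fraction of the image side) for each head map.
#' @param ratios prior aspect ratios per cell.
#' @param variances offset-encoding variances `(v_center, v_size)`.
#' @param iou_threshold prior/ground-truth matching threshold.
#' @param nms_iou_threshold suppression overlap used at inference.
#' @param top_k maximum detections retained per image.
#' @param neg_pos_ratio hard-negative mining ratio for the confidence loss.
#' @param alpha localization loss weight.
#' @return an `ssd_config` list, including the derived `prior_box_set`.
#' @export
ssd_config <- function(input_size = 300L,
                       base_channels = c(8L, 16L, 32L, 64L),
                       head_layers = c(3L, 4L),
                       scales = c(0.03, 0.05),
                       ratios = c(1, 2, 0.5),
                       variances = c(0.1, 0.2),
                       iou_threshold = 0.5,
                       nms_iou_threshold = 0.45,
                       top_k = 200L,
                       neg_pos_ratio = 3,
                       alpha = 1) {
  if (length(head_layers) != length(scales)) {
    stopf("one prior scale is required per head layer")
  }
  if (any(head_layers > length(base_channels))) {
    stopf("head_layers index beyond the backbone depth")
  }
  sizes <- integer(length(base_channels))
  s <- as.integer(input_size)
  for (l in seq_along(base_channels)) {
    s <- conv_out_size(s)
    sizes[l] <- s
  }
  grids <- sizes[head_layers]
  priors <- generate_priors(prior_config(grids, scales, ratios, variances))
  structure(list(input_size = as.integer(input_size),
                 base_channels = as.integer(base_channels),
                 head_layers = as.integer(head_layers),
                 map_sizes = sizes,
                 scales = scales, ratios = ratios, variances = variances,
                 iou_threshold = iou_threshold,
                 nms_iou_threshold = nms_iou_threshold,
                 top_k = as.integer(top_k),
                 neg_pos_ratio = neg_pos_ratio, alpha = alpha,
                 priors = priors),
            class = "ssd_config")
}

# He-initialized weights. Head class biases start with a high background
# logit so that the untrained detector predicts background almost
# everywhere, which keeps the mined confidence loss finite and stable.
net_init <- function(config, seed = NULL) {
  with_seed(seed, {
    n_ratios <- length(config$ratios)
    in_ch <- 1L
    base <- list()
    for (l in seq_along(config$base_channels)) {
      out_ch <- config$base_channels[l]
      fan_in <- 9L * in_ch
      base[[l]] <- list(
        W = matrix(rnorm(fan_in * out_ch, sd = sqrt(2 / fan_in)),
                   fan_in, out_ch),
        b = numeric(out_ch))
      in_ch <- out_ch
    }
    heads <- list()
    for (h in seq_along(config$head_layers)) {
      m <- config$head_layers[h]
      ch <- config$base_channels[m]
      fan_in <- 9L * ch
      out_ch <- 6L * n_ratios
      b <- numeric(out_ch)
      # per ratio group rows 1:2 are (background, stoma) logits
      b[(seq_len(n_ratios) - 1L) * 6L + 1L] <- log(99)
      heads[[h]] <- list(
        W = matrix(rnorm(fan_in * out_ch, sd = sqrt(2 / fan_in) * 0.1),
                   fan_in, out_ch),
        b = b,
        after = m, grid = config$map_sizes[m])
    }
    list(base = base, heads = heads)
  })
}

# Per-image mean centering at the network input: detection should not
# depend on the absolute gray level of a micrograph (illumination and
# replica opacity vary between acquisitions), so the brightness component
# of any domain shift is removed before the first convolution.
prep_raster <- function(img) img - mean(img)

# Forward pass over a batch. x: array (h, w, 1, n). Returns head output
# matrices (6*n_ratios x grid^2*n) and, optionally, the caches needed for
# backpropagation.
net_forward <- function(net, config, x, keep_cache = FALSE) {
  n <- dim(x)[4]
  a <- x
  caches <- vector("list", length(net$base))
  acts <- vector("list", length(net$base))
  for (l in seq_along(net$base)) {
    d <- dim(a)
    cols <- im2col_cpp(a, 3L, 2L, 1L)
    z <- crossprod(net$base[[l]]$W, cols) + net$base[[l]]$b
    mask <- z > 0
    zm <- z * mask
    oh <- conv_out_size(d[1])
    ow <- conv_out_size(d[2])
    out_ch <- ncol(net$base[[l]]$W)
    a <- aperm(array(zm, dim = c(out_ch, oh, ow, n)), c(2, 3, 1, 4))
    if (keep_cache) {
      caches[[l]] <- list(cols = cols, mask = mask, in_dim = d,
                          out_dim = c(oh, ow, out_ch, n))
    } else {
      caches[[l]] <- list(in_dim = d, out_dim = c(oh, ow, out_ch, n))
    }
    acts[[l]] <- a
  }
  head_outs <- vector("list", length(net$heads))
  head_caches <- vector("list", length(net$heads))
  for (h in seq_along(net$heads)) {
    m <- net$heads[[h]]$after
    am <- acts[[m]]
    cols <- im2col_cpp(am, 3L, 1L, 1L)
    head_outs[[h]] <- crossprod(net$heads[[h]]$W, cols) + net$heads[[h]]$b
    if (keep_cache) {
      head_caches[[h]] <- list(cols = cols, in_dim = dim(am))
    }
  }
  list(heads = head_outs, caches = caches, head_caches = head_caches,
       n = n)
}

# Backward pass: d_heads are gradients w.r.t. the head output matrices.
# Returns gradients with the same structure as the network parameters.
net_backward <- function(net, config, fwd, d_heads) {
  n <- fwd$n
  grads <- list(base = vector("list", length(net$base)),
                heads = vector("list", length(net$heads)))
  # accumulated gradient flowing into each backbone activation
  da <- vector("list", length(net$base))
  for (h in seq_along(net$heads)) {
    m <- net$heads[[h]]$after
    dout <- d_heads[[h]]
    cols <- fwd$head_caches[[h]]$cols
    grads$heads[[h]] <- list(W = cols %*% t(dout), b = rowSums(dout))
    dcols <- net$heads[[h]]$W %*% dout
    d <- fwd$head_caches[[h]]$in_dim
    dm <- col2im_cpp(dcols, d[1], d[2], d[3], d[4], 3L, 1L, 1L)
    da[[m]] <- if (is.null(da[[m]])) dm else da[[m]] + dm
  }
  for (l in rev(seq_along(net$base))) {
    cache <- fwd$caches[[l]]
    od <- cache$out_dim
    if (is.null(da[[l]])) {
      grads$base[[l]] <- list(W = net$base[[l]]$W * 0,
                              b = numeric(length(net$base[[l]]$b)))
      next
    }
    # array (oh, ow, ch, n) -> matrix (ch, oh*ow*n) matching z's layout
    da_mat <- aperm(da[[l]], c(3, 1, 2, 4))
    dim(da_mat) <- c(od[3], od[1] * od[2] * od[4])
    dz <- da_mat * cache$mask
    grads$base[[l]] <- list(W = cache$cols %*% t(dz), b = rowSums(dz))
    if (l > 1L) {
      dcols <- net$base[[l]]$W %*% dz
      d <- cache$in_dim
      dprev <- col2im_cpp(dcols, d[1], d[2], d[3], d[4], 3L, 2L, 1L)
      da[[l - 1L]] <- if (is.null(da[[l - 1L]])) dprev else
        da[[l - 1L]] + dprev
    }
  }
  grads
}

# Gather per-image prediction sets (scores P x 2, offsets P x 4, prior
# order = (map, ratio, cell)) from the head output matrices.
pred_from_heads <- function(head_outs, config, n) {
  n_ratios <- length(config$ratios)
  total <- nrow(config$priors$centers)
  scores <- matrix(0, total * n, 2)
  offsets <- matrix(0, total * n, 4)
  offset_m <- 0L
  for (h in seq_along(head_outs)) {
    g2 <- config$priors$layout[[h]]$grid^2
    out <- head_outs[[h]]
    im_idx <- rep(seq_len(n), each = g2)
    cell_idx <- rep(seq_len(g2), times = n)
    for (r in seq_len(n_ratios)) {
      rows <- (im_idx - 1L) * total + offset_m + (r - 1L) * g2 + cell_idx
      base_row <- (r - 1L) * 6L
      scores[rows, 1] <- out[base_row + 1L, ]
      scores[rows, 2] <- out[base_row + 2L, ]
      for (k in 1:4) offsets[rows, k] <- out[base_row + 2L + k, ]
    }
    offset_m <- offset_m + g2 * n_ratios
  }
  list(scores = scores, offsets = offsets, n_priors = total)
}

# Scatter per-prior gradients back into head-output-shaped matrices.
heads_from_grads <- function(d_scores, d_offsets, config, n) {
  n_ratios <- length(config$ratios)
  total <- nrow(config$priors$centers)
  d_heads <- list()
  offset_m <- 0L
  for (h in seq_along(config$priors$layout)) {
    g2 <- config$priors$layout[[h]]$grid^2
    dout <- matrix(0, 6L * n_ratios, g2 * n)
    im_idx <- rep(seq_len(n), each = g2)
    cell_idx <- rep(seq_len(g2), times = n)
    for (r in seq_len(n_ratios)) {
      rows <- (im_idx - 1L) * total + offset_m + (r - 1L) * g2 + cell_idx
      base_row <- (r - 1L) * 6L
      dout[base_row + 1L, ] <- d_scores[rows, 1]
      dout[base_row + 2L, ] <- d_scores[rows, 2]
      for (k in 1:4) dout[base_row + 2L + k, ] <- d_offsets[rows, k]
    }
    d_heads[[h]] <- dout
    offset_m <- offset_m + g2 * n_ratios
  }
  d_heads
}

# Adam optimizer over the nested parameter list.
adam_init <- function(net) {
  zeros <- function(p) list(m = p * 0, v = p * 0)
  list(base = lapply(net$base, function(l) list(W = zeros(l$W), b = zeros(l$b))),
       heads = lapply(net$heads, function(l) list(W = zeros(l$W), b = zeros(l$b))),
       t = 0L)
}

adam_step <- function(net, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- function(p, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    p <- p - lr * (s$m / corr1) / (sqrt(s$v / corr2) + eps)
    list(p = p, s = s)
  }
  for (l in seq_along(net$base)) {
    r <- upd(net$base[[l]]$W, grads$base[[l]]$W, state$base[[l]]$W)
    net$base[[l]]$W <- r$p; state$base[[l]]$W <- r$s
    r <- upd(net$base[[l]]$b, grads$base[[l]]$b, state$base[[l]]$b)
    net$base[[l]]$b <- r$p; state$base[[l]]$b <- r$s
  }
  for (h in seq_along(net$heads)) {
    r <- upd(net$heads[[h]]$W, grads$heads[[h]]$W, state$heads[[h]]$W)
    net$heads[[h]]$W <- r$p; state$heads[[h]]$W <- r$s
    r <- upd(net$heads[[h]]$b, grads$heads[[h]]$b, state$heads[[h]]$b)
    net$heads[[h]]$b <- r$p; state$heads[[h]]$b <- r$s
  }
  list(net = net, state = state)
}
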