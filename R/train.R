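# Fitting the stomata detector and running inference with it.

# Coerce training input (synthetic scenes, annotated images, or a manifest
# data frame with path/xml columns) into a list of annotated images with
# loaded rasters at the detector input size.
as_training_scenes <- function(x, input_size) {
  if (is.data.frame(x)) {
    x <- lapply(seq_len(nrow(x)), function(i) {
      ann <- read_voc_annotation(x$xml[i])
      ann$image <- read_micrograph(x$path[i])
      ann$image_path <- x$path[i]
      ann
    })
  }
  if (inherits(x, "annotated_image")) x <- list(x)
  lapply(x, function(ann) {
    stopifnot(inherits(ann, "annotated_image"))
    resize_image_and_boxes(ann, input_size)
  })
}

# Per-scene training targets are fixed by the geometry, so matching is
# done once up front rather than every epoch. With augmentation, targets
# for the four flip variants (identity, horizontal, vertical, both) are
# precomputed as well.
flip_boxes <- function(b, flip_h, flip_v) {
  out <- b
  if (flip_h) {
    out[, 1] <- 1 - b[, 3]
    out[, 3] <- 1 - b[, 1]
  }
  if (flip_v) {
    out[, 2] <- 1 - b[, 4]
    out[, 4] <- 1 - b[, 2]
  }
  out
}

flip_raster <- function(img, flip_h, flip_v) {
  if (flip_h) img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
  if (flip_v) img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  img
}

flip_variants <- cbind(h = c(FALSE, TRUE, FALSE, TRUE),
                       v = c(FALSE, FALSE, TRUE, TRUE))

precompute_matches <- function(scenes, config, augment = FALSE) {
  n_var <- if (augment) 4L else 1L
  lapply(scenes, function(ann) {
    gt <- box_matrix(ann$boxes) / config$input_size
    lapply(seq_len(n_var), function(v) {
      g <- if (nrow(ann$boxes)) {
        flip_boxes(gt, flip_variants[v, 1], flip_variants[v, 2])
      } else NULL
      match_priors(g, config$priors, config$iou_threshold)
    })
  })
}

#' Train the stomata detector
#'
#' Fits the desk-scale single-shot multibox detector: for `epochs` full
#' passes over the training images (seeded shuffle, mini-batch Adam), the
#' multibox loss is minimized end-to-end. Fifty epochs is the default
#' training length of the phenotyping protocol.
#'
#' @param scenes training data: a list of annotated images /
#'   `synthetic_scene`s, or a manifest data frame with `path` and `xml`
#'   columns.
#' @param size number of training images actually used: the first `size`
#'   images of a seeded shuffle of `scenes` (default: all). This is the
#'   training-set-size axis of the model-selection sweep.
#' @param epochs full passes over the training subset (default 50).
#' @param seed RNG seed fixing the shuffle, the weight initialization and
#'   the batch order.
#' @param config an [ssd_config()].
#' @param lr,batch_size Adam learning rate and mini-batch size.
#' @param augment if `TRUE`, each image is presented under a random flip
#'   (horizontal/vertical) every epoch; stomata carry no preferred
#'   orientation, so flips are label-preserving. Off by default: the
#'   generator already supplies abundant positive examples.
#' @param basal optional `ssd_model` whose weights initialize this fit
#'   (fine-tuning); its architecture must match `config`.
#' @param verbose print per-epoch loss.
#' @return an `ssd_model` object with the fitted weights, the prior
#'   configuration, the per-epoch loss trajectory and full provenance.
#' @export
train_detector <- function(scenes, size = NULL, epochs = 50L, seed = 1L,
                           config = ssd_config(), lr = 2e-3,
                           batch_size = 8L, augment = FALSE, basal = NULL,
                           verbose = FALSE) {
  if (!is_count(epochs)) stopf("epochs must be a non-negative integer")
  scenes <- as_training_scenes(scenes, config$input_size)
  n_pool <- length(scenes)
  if (!is.null(size)) {
    if (size > n_pool) {
      stopf("requested %d training images but the pool has %d", size, n_pool)
    }
  } else {
    size <- n_pool
  }
  if (size < 1L) stopf("training needs at least one image")
  net <- if (is.null(basal)) {
    net_init(config, seed = seed)
  } else {
    stopifnot(inherits(basal, "ssd_model"))
    if (!identical(basal$config$base_channels, config$base_channels) ||
        !identical(basal$config$input_size, config$input_size) ||
        !identical(basal$config$head_layers, config$head_layers)) {
      stopf("basal model architecture does not match the requested config")
    }
    basal$net
  }
  loss_history <- numeric(0)
  with_seed(seed, {
    sel <- sample.int(n_pool)[seq_len(size)]
    scenes <- scenes[sel]
    matches <- precompute_matches(scenes, config, augment = augment)
    rasters <- lapply(scenes, function(s) s$image)
    state <- adam_init(net)
    sz <- config$input_size
    for (ep in seq_len(epochs)) {
      ord <- sample.int(size)
      ep_loss <- 0
      n_batches <- 0L
      for (start in seq(1L, size, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, size)]
        nb <- length(idx)
        variant <- if (augment) sample.int(4L, nb, replace = TRUE) else
          rep(1L, nb)
        x <- array(0, dim = c(sz, sz, 1L, nb))
        for (k in seq_len(nb)) {
          x[, , 1L, k] <- prep_raster(flip_raster(rasters[[idx[k]]],
                                                  flip_variants[variant[k], 1],
                                                  flip_variants[variant[k], 2]))
        }
        fwd <- net_forward(net, config, x, keep_cache = TRUE)
        pred <- pred_from_heads(fwd$heads, config, nb)
        P <- pred$n_priors
        d_scores <- matrix(0, P * nb, 2)
        d_offsets <- matrix(0, P * nb, 4)
        batch_loss <- 0
        for (k in seq_len(nb)) {
          rows <- (k - 1L) * P + seq_len(P)
          ls <- multibox_loss(list(scores = pred$scores[rows, , drop = FALSE],
                                   offsets = pred$offsets[rows, , drop = FALSE]),
                              matches[[idx[k]]][[variant[k]]],
                              neg_pos_ratio = config$neg_pos_ratio,
                              alpha = config$alpha, gradient = TRUE)
          batch_loss <- batch_loss + ls$total
          d_scores[rows, ] <- ls$d_scores / nb
          d_offsets[rows, ] <- ls$d_offsets / nb
        }
        d_heads <- heads_from_grads(d_scores, d_offsets, config, nb)
        grads <- net_backward(net, config, fwd, d_heads)
        st <- adam_step(net, grads, state, lr = lr)
        net <- st$net
        state <- st$state
        ep_loss <- ep_loss + batch_loss / nb
        n_batches <- n_batches + 1L
      }
      loss_history[ep] <- ep_loss / n_batches
      if (verbose) {
        message(sprintf("epoch %d/%d  loss %.4f", ep, epochs,
                        loss_history[ep]))
      }
    }
  })
  structure(list(net = net, config = config, input_size = config$input_size,
                 n_train = size, epochs = epochs, seed = seed, lr = lr,
                 batch_size = batch_size, loss_history = loss_history,
                 basal = if (!is.null(basal)) basal$provenance else NULL,
                 provenance = sprintf(
                   "ssd_model(n_train=%d, epochs=%d, seed=%d%s)",
                   size, epochs, seed,
                   if (!is.null(basal)) ", fine-tuned" else "")),
            class = "ssd_model")
}

#' Fine-tune a basal detector on a new imaging domain
#'
#' Continues training from the weights of an existing (basal) model on a
#' small annotated set from the new domain -- the standard way to adapt
#' the detector when leaf morphology or image texture shifts (e.g. a
#' different growth stage or acquisition protocol). With `epochs = 0` the
#' returned weights are identical to the basal model.
#'
#' @param basal_model the fitted `ssd_model` to start from.
#' @param scenes annotated images from the new domain (the protocol used
#'   45 images).
#' @param epochs additional training epochs (default 50).
#' @param lr fine-tuning learning rate (default a quarter of the
#'   from-scratch training rate).
#' @param seed RNG seed.
#' @param ... passed to [train_detector()].
#' @return a fine-tuned `ssd_model` whose provenance records the basal fit.
#' @export
fine_tune <- function(basal_model, scenes, epochs = 50L, lr = 5e-4,
                      seed = 1L, ...) {
  stopifnot(inherits(basal_model, "ssd_model"))
  train_detector(scenes, epochs = epochs, seed = seed, lr = lr,
                 config = basal_model$config, basal = basal_model, ...)
}

#' @export
print.ssd_model <- function(x, ...) {
  cat("Single-shot stomata detector\n")
  cat(sprintf("  input %dx%d px, %d priors, %d backbone layers\n",
              x$input_size, x$input_size, nrow(x$config$priors$centers),
              length(x$net$base)))
  cat(sprintf("  trained on %d image(s) for %d epoch(s), seed %d%s\n",
              x$n_train, x$epochs, x$seed,
              if (!is.null(x$basal)) paste0("\n  fine-tuned from ", x$basal)
              else ""))
  if (length(x$loss_history)) {
    cat(sprintf("  final training loss %.4f\n",
                x$loss_history[length(x$loss_history)]))
  }
  invisible(x)
}

#' @export
summary.ssd_model <- function(object, ...) {
  n_par <- sum(vapply(object$net$base,
                      function(l) length(l$W) + length(l$b), numeric(1))) +
    sum(vapply(object$net$heads,
               function(l) length(l$W) + length(l$b), numeric(1)))
  out <- list(n_parameters = n_par,
              n_priors = nrow(object$config$priors$centers),
              n_train = object$n_train, epochs = object$epochs,
              loss_history = object$loss_history,
              fine_tuned = !is.null(object$basal))
  class(out) <- "summary.ssd_model"
  out
}

#' @export
print.summary.ssd_model <- function(x, ...) {
  cat(sprintf("SSD stomata detector: %d parameters, %d priors\n",
              x$n_parameters, x$n_priors))
  cat(sprintf("  %d training images, %d epochs%s\n", x$n_train, x$epochs,
              if (x$fine_tuned) " (fine-tuned)" else ""))
  if (length(x$loss_history)) {
    cat(sprintf("  loss: first %.4f  last %.4f\n", x$loss_history[1],
                x$loss_history[length(x$loss_history)]))
  }
  invisible(x)
}

as_detect_input <- function(image) {
  if (inherits(image, "annotated_image")) {
    img <- image$image
    if (is.null(img) && !is.null(image$image_path)) {
      img <- read_micrograph(image$image_path)
    }
    img
  } else if (is.character(image)) {
    read_micrograph(image)
  } else {
    as.matrix(image)
  }
}

#' Detect stomata in a micrograph
#'
#' Runs the forward pass, decodes the prior-relative offsets, keeps
#' candidates whose stoma probability is strictly greater than the
#' confidence threshold `c_st`, and applies greedy non-maximum
#' suppression. Detections are returned in the pixel coordinates of the
#' supplied image.
#'
#' @param image grayscale matrix in `[0,1]`, an [annotated_image()], or a
#'   file path. Rasters that are not at the detector input size are
#'   resized internally (counts are unaffected).
#' @param model a fitted `ssd_model`.
#' @param c_st confidence threshold in (0, 1); the protocol's calibrated
#'   default on greenhouse-type imagery is 0.30.
#' @return a detection data frame (`xmin, ymin, xmax, ymax, score`) with
#'   attribute `c_st`.
#' @export
detect <- function(image, model, c_st = 0.3) {
  stopifnot(inherits(model, "ssd_model"))
  if (!is.numeric(c_st) || length(c_st) != 1L || c_st <= 0 || c_st >= 1) {
    stopf("c_st must be a single value in (0, 1); the protocol requires > 0")
  }
  img <- as_detect_input(image)
  native <- dim(img)
  sz <- model$input_size
  if (!all(native == c(sz, sz))) {
    img <- resize_bilinear_cpp(img, sz, sz)
  }
  x <- array(prep_raster(img), dim = c(sz, sz, 1L, 1L))
  fwd <- net_forward(model$net, model$config, x, keep_cache = FALSE)
  pred <- pred_from_heads(fwd$heads, model$config, 1L)
  probs <- softmax_probs(pred$scores)[, 2]
  keep <- which(probs > c_st)
  empty <- data.frame(xmin = numeric(0), ymin = numeric(0),
                      xmax = numeric(0), ymax = numeric(0),
                      score = numeric(0))
  if (length(keep) == 0L) {
    attr(empty, "c_st") <- c_st
    return(empty)
  }
  dec <- decode_boxes(pred$offsets[keep, , drop = FALSE],
                      model$config$priors$centers[keep, , drop = FALSE],
                      model$config$variances)
  dec <- pmin(pmax(dec, 0), 1)
  dim(dec) <- c(length(keep), 4L)
  ok <- dec[, 3] > dec[, 1] & dec[, 4] > dec[, 2]
  if (!any(ok)) {
    attr(empty, "c_st") <- c_st
    return(empty)
  }
  dec <- dec[ok, , drop = FALSE]
  det <- data.frame(xmin = dec[, 1] * native[2], ymin = dec[, 2] * native[1],
                    xmax = dec[, 3] * native[2], ymax = dec[, 4] * native[1],
                    score = probs[keep][ok])
  det <- nms(det, model$config$nms_iou_threshold, model$config$top_k)
  rownames(det) <- NULL
  attr(det, "c_st") <- c_st
  det
}

#' @rdname detect
#' @param object,newdata,... `predict` method interface: `newdata` is one
#'   image or a list of images.
#' @export
predict.ssd_model <- function(object, newdata, c_st = 0.3, ...) {
  if (is.list(newdata) && !inherits(newdata, "annotated_image") &&
      !is.matrix(newdata)) {
    lapply(newdata, detect, model = object, c_st = c_st)
  } else {
    detect(newdata, object, c_st = c_st)
  }
}

#' Count stomata in an image
#'
#' The automated replacement for manual counting: the number of
#' detections at the given confidence threshold.
#'
#' @inheritParams detect
#' @return integer count.
#' @export
count_stomata <- function(image, model, c_st = 0.3) {
  nrow(detect(image, model, c_st))
}

#' Plot detections over a micrograph
#'
#' Renders the image with detection boxes outlined (the usual visual check
#' of detector output quality), optionally alongside ground-truth boxes.
#'
#' @param x a fitted `ssd_model`.
#' @param image image accepted by [detect()].
#' @param c_st confidence threshold.
#' @param gt_boxes optional ground-truth box table drawn dashed.
#' @param ... ignored.
#' @return the detection table, invisibly.
#' @export
plot.ssd_model <- function(x, image, c_st = 0.3, gt_boxes = NULL, ...) {
  img <- as_detect_input(image)
  det <- detect(img, x, c_st)
  h <- nrow(img); w <- ncol(img)
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(0, w), ylim = c(h, 0), asp = 1, axes = FALSE,
                 xlab = "", ylab = "",
                 main = sprintf("%d detections at C_st = %.2f",
                                nrow(det), c_st))
  graphics::rasterImage(grDevices::as.raster(pmin(pmax(img, 0), 1)),
                        0, h, w, 0)
  if (nrow(det)) {
    graphics::rect(det$xmin, det$ymin, det$xmax, det$ymax,
                   border = "orange", lwd = 1.5)
  }
  if (!is.null(gt_boxes) && nrow(gt_boxes)) {
    graphics::rect(gt_boxes$xmin, gt_boxes$ymin, gt_boxes$xmax,
                   gt_boxes$ymax, border = "deepskyblue", lty = 2)
  }
  invisible(det)
}

#' Save / load a fitted detector
#'
#' The checkpoint is a JSON file holding the weights and the full prior /
#' architecture configuration, so it is text, portable and diffable.
#'
#' @param model an `ssd_model`.
#' @param path checkpoint path (`.json`).
#' @return `save_model`: the path, invisibly. `load_model`: the restored
#'   `ssd_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ssd_model"))
  payload <- list(
    config = list(input_size = model$config$input_size,
                  base_channels = model$config$base_channels,
                  head_layers = model$config$head_layers,
                  scales = model$config$scales,
                  ratios = model$config$ratios,
                  variances = model$config$variances,
                  iou_threshold = model$config$iou_threshold,
                  nms_iou_threshold = model$config$nms_iou_threshold,
                  top_k = model$config$top_k,
                  neg_pos_ratio = model$config$neg_pos_ratio,
                  alpha = model$config$alpha),
    n_train = model$n_train, epochs = model$epochs, seed = model$seed,
    loss_history = model$loss_history, basal = model$basal,
    provenance = model$provenance,
    base = lapply(model$net$base, function(l)
      list(W = as.numeric(l$W), dim = dim(l$W), b = l$b)),
    heads = lapply(model$net$heads, function(l)
      list(W = as.numeric(l$W), dim = dim(l$W), b = l$b,
           after = l$after, grid = l$grid)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(ssd_config, p$config)
  rebuild <- function(l) {
    out <- list(W = matrix(unlist(l$W), unlist(l$dim)[1], unlist(l$dim)[2]),
                b = as.numeric(unlist(l$b)))
    if (!is.null(l$after)) {
      out$after <- as.integer(unlist(l$after))
      out$grid <- as.integer(unlist(l$grid))
    }
    out
  }
  base <- if (is.data.frame(p$base)) {
    lapply(seq_len(nrow(p$base)), function(i) rebuild(p$base[i, ]))
  } else lapply(p$base, rebuild)
  heads <- if (is.data.frame(p$heads)) {
    lapply(seq_len(nrow(p$heads)), function(i) rebuild(p$heads[i, ]))
  } else lapply(p$heads, rebuild)
  structure(list(net = list(base = base, heads = heads), config = cfg,
                 input_size = cfg$input_size, n_train = p$n_train,
                 epochs = p$epochs, seed = p$seed,
                 loss_history = p$loss_history,
                 basal = p$basal, provenance = p$provenance),
            class = "ssd_model")
}
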