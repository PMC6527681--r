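# Multibox training objective: smooth-L1 localization loss on positive
# priors plus softmax cross-entropy confidence loss with hard negative
# mining, normalized by the number of matched priors.

smooth_l1 <- function(x) {
  ax <- abs(x)
  ifelse(ax < 1, 0.5 * x * x, ax - 0.5)
}

smooth_l1_grad <- function(x) {
  pmax(pmin(x, 1), -1)
}

# Row-wise stable softmax cross-entropy. scores: n x 2 logits (background,
# stoma); class: 1 = background, 2 = stoma. Returns per-row loss.
softmax_xent <- function(scores, class) {
  m <- pmax(scores[, 1], scores[, 2])
  lse <- m + log(exp(scores[, 1] - m) + exp(scores[, 2] - m))
  lse - scores[cbind(seq_len(nrow(scores)), class)]
}

softmax_probs <- function(scores) {
  m <- pmax(scores[, 1], scores[, 2])
  e1 <- exp(scores[, 1] - m)
  e2 <- exp(scores[, 2] - m)
  cbind(e1 / (e1 + e2), e2 / (e1 + e2))
}

#' Multibox loss
#'
#' Combined detection objective over one image (or a batch flattened into
#' one prior list): `total = (L_conf + alpha * L_loc) / N` where `N` is the
#' number of matched (positive) priors. `L_loc` is the smooth-L1 loss
#' between predicted offsets and encoded targets on positive priors;
#' `L_conf` is softmax cross-entropy on the positives plus the hardest
#' negatives, selected by their background confidence loss at
#' `neg_pos_ratio` negatives per positive. With zero positives the loss is
#' defined as 0.
#'
#' @param prediction_set list with `scores` (P x 2 logits, columns
#'   background/stoma) and `offsets` (P x 4).
#' @param match_result a [match_priors()] result over the same priors.
#' @param neg_pos_ratio hard-negative mining ratio (default 3).
#' @param alpha localization weight (default 1).
#' @param gradient if `TRUE`, also return gradients of the total loss with
#'   respect to `scores` and `offsets`.
#' @return list with `total`, `confidence`, `localization` (and `d_scores`,
#'   `d_offsets` when `gradient = TRUE`).
#' @export
multibox_loss <- function(prediction_set, match_result, neg_pos_ratio = 3,
                          alpha = 1, gradient = FALSE) {
  if (neg_pos_ratio < 0) stopf("neg_pos_ratio must be non-negative")
  scores <- prediction_set$scores
  offsets <- prediction_set$offsets
  n_priors <- nrow(scores)
  if (n_priors != length(match_result$assignment)) {
    stopf("predictions and match result cover different prior sets")
  }
  pos <- match_result$positive
  n_pos <- length(pos)
  zero <- list(total = 0, confidence = 0, localization = 0)
  if (n_pos == 0L) {
    if (gradient) {
      zero$d_scores <- matrix(0, n_priors, 2)
      zero$d_offsets <- matrix(0, n_priors, 4)
    }
    return(zero)
  }
  # localization on positives
  diff <- offsets[pos, , drop = FALSE] - match_result$targets
  l_loc <- sum(smooth_l1(diff))
  # confidence: positives as stoma, mined hardest negatives as background
  neg <- which(match_result$assignment == 0L)
  neg_losses <- softmax_xent(scores[neg, , drop = FALSE],
                             rep(1L, length(neg)))
  n_neg <- min(length(neg), floor(neg_pos_ratio * n_pos))
  hard_neg <- if (n_neg > 0L) neg[order(-neg_losses,
                                        seq_along(neg))[seq_len(n_neg)]]
              else integer(0)
  pos_losses <- softmax_xent(scores[pos, , drop = FALSE], rep(2L, n_pos))
  hard_losses <- if (n_neg > 0L)
    softmax_xent(scores[hard_neg, , drop = FALSE], rep(1L, n_neg))
  else numeric(0)
  l_conf <- sum(pos_losses) + sum(hard_losses)
  out <- list(total = (l_conf + alpha * l_loc) / n_pos,
              confidence = l_conf, localization = l_loc)
  if (gradient) {
    d_scores <- matrix(0, n_priors, 2)
    sel <- c(pos, hard_neg)
    cls <- c(rep(2L, n_pos), rep(1L, n_neg))
    p <- softmax_probs(scores[sel, , drop = FALSE])
    p[cbind(seq_along(sel), cls)] <- p[cbind(seq_along(sel), cls)] - 1
    d_scores[sel, ] <- p / n_pos
    d_offsets <- matrix(0, n_priors, 4)
    d_offsets[pos, ] <- alpha * smooth_l1_grad(diff) / n_pos
    out$d_scores <- d_scores
    out$d_offsets <- d_offsets
  }
  out
}
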