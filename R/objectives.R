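# Training objectives: multi-class cross-entropy, soft Dice, and their
# convex combination. Plain-array versions are the public API; the fused
# autodiff op (logits -> scalar loss) carries an analytic gradient through
# the per-pixel softmax.

as_prob_matrix <- function(prob) {
  d <- dim(prob)
  if (length(d) == 3L) d <- c(d, 1L)
  stopifnot(length(d) == 4L)
  pm <- aperm(array(prob, d), c(1, 2, 4, 3))
  dim(pm) <- c(d[1] * d[2] * d[4], d[3])
  pm
}

check_loss_shapes <- function(prob, labels) {
  dp <- dim(prob); dl <- dim(labels) %||% length(labels)
  if (length(dp) == 3L) dp <- c(dp, 1L)
  if (length(dl) == 2L) dl <- c(dl, 1L)
  if (!all(dp[c(1, 2, 4)] == dl)) {
    stop("probability map and label mask shapes disagree", call. = FALSE)
  }
  dp
}

#' Multi-class cross-entropy loss
#'
#' Computes \eqn{-\frac{1}{N}\sum_i\sum_c L_{i,c}\log P_{i,c}} over all
#' pixels, where the ground truth enters one-hot encoded. Probabilities are
#' clamped below at `1e-12` before the logarithm so a zero probability at a
#' true class yields a large finite value rather than `Inf`.
#'
#' @param prob array of per-class probabilities, `(H, W, C)` or `(H, W, C, B)`.
#' @param labels integer array of class indices in `0..C-1`, `(H, W)` or
#'   `(H, W, B)`.
#' @return scalar loss.
#' @export
cross_entropy_loss <- function(prob, labels) {
  check_loss_shapes(prob, labels)
  pm <- as_prob_matrix(prob)
  idx <- cbind(seq_len(nrow(pm)), as.vector(labels) + 1L)
  -mean(log(pmax(pm[idx], 1e-12)))
}

#' Soft Dice loss
#'
#' One minus the mean over classes of the soft Dice coefficient
#' \eqn{2\sum_i P_{i,c} L_{i,c} / (\sum_i P_{i,c} + \sum_i L_{i,c})},
#' computed per class over all pixels and averaged. No smoothing constant is
#' added to the numerator; a small `eps` guards the denominator only, so that
#' a class absent from both prediction mass and ground truth contributes a
#' zero-overlap (Dice 0) term rather than dividing by zero.
#'
#' @inheritParams cross_entropy_loss
#' @param eps denominator guard, default `1e-6`.
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(prob, labels, eps = 1e-6) {
  d <- check_loss_shapes(prob, labels)
  pm <- as_prob_matrix(prob)
  C <- d[3]
  lv <- as.vector(labels)
  dices <- vapply(seq_len(C), function(c) {
    y <- as.numeric(lv == (c - 1L))
    p <- pm[, c]
    2 * sum(p * y) / (sum(p) + sum(y) + eps)
  }, numeric(1))
  1 - mean(dices)
}

#' Hybrid segmentation loss
#'
#' \eqn{\lambda L_{CE} + (1-\lambda) L_{Dice}}. The defaults used by the
#' bundled training profiles are \eqn{\lambda = 0.4} for multi-organ and
#' cardiac segmentation and \eqn{\lambda = 0.5} for binary lesion
#' segmentation.
#'
#' @inheritParams cross_entropy_loss
#' @param lambda mixing weight in `[0, 1]`.
#' @return scalar loss.
#' @export
hybrid_loss <- function(prob, labels, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  }
  lambda * cross_entropy_loss(prob, labels) +
    (1 - lambda) * dice_loss(prob, labels)
}

#' Softmax over the class axis of a logits array
#' @param logits array `(H, W, C)` or `(H, W, C, B)`.
#' @return array of probabilities with the same shape.
#' @export
softmax_probs <- function(logits) {
  d <- dim(logits)
  nd <- length(d)
  cd <- 3L
  xm <- aperm(logits, c(setdiff(seq_len(nd), cd), cd))
  C <- d[cd]
  dim(xm) <- c(prod(d) / C, C)
  mx <- xm[, 1]
  for (j in seq_len(C)[-1]) mx <- pmax(mx, xm[, j])
  e <- exp(xm - mx)
  p <- e / rowSums(e)
  dim(p) <- c(d[setdiff(seq_len(nd), cd)], C)
  aperm(p, order(c(setdiff(seq_len(nd), cd), cd)))
}

# Fused autodiff loss: logits (H, W, C, B) + integer labels -> scalar.
# Analytic gradient: lambda*(P - Y)/N for the cross-entropy part, and the
# soft-Dice derivative chained through the softmax Jacobian for the rest.
op_seg_loss <- function(logits, labels, lambda, eps = 1e-6) {
  lv <- logits$value
  d <- dim(lv)
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  K <- H * W * B
  xm <- aperm(lv, c(1, 2, 4, 3)); dim(xm) <- c(K, C)
  mx <- xm[, 1]
  for (j in seq_len(C)[-1]) mx <- pmax(mx, xm[, j])
  e <- exp(xm - mx)
  P <- e / rowSums(e)
  yidx <- as.vector(labels) + 1L
  ce <- -mean(log(pmax(P[cbind(seq_len(K), yidx)], 1e-12)))
  Y <- matrix(0, K, C); Y[cbind(seq_len(K), yidx)] <- 1
  num <- 2 * colSums(P * Y)
  den <- colSums(P) + colSums(Y) + eps
  dice_terms <- num / den
  ldice <- 1 - mean(dice_terms)
  loss <- lambda * ce + (1 - lambda) * ldice
  node <- ad_op(array(loss, 1L), list(logits), function(g) {
    gs <- as.numeric(g)
    dP <- -(1 / C) * sweep(sweep(2 * Y, 2, den, "/"), 2, num / den^2, "-")
    # chain dice part through softmax
    dot <- rowSums(dP * P)
    dl_dice <- P * (dP - dot)
    dl <- lambda * (P - Y) / K + (1 - lambda) * dl_dice
    dl <- dl * gs
    dim(dl) <- c(H, W, B, C)
    list(aperm(dl, c(1, 2, 4, 3)))
  })
  node$aux <- list(ce = ce, dice = ldice)
  node
}
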