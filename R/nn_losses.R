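# Training losses. Both return the scalar loss together with its gradient
# with respect to the logits, so the network backward pass starts from a
# single array.

#' One-hot encode a network-grid label map
#'
#' @param mask2d integer label matrix.
#' @param kind sequence kind; classes follow [kind_labels()] order.
#' @return array dim (H, W, n_classes) of 0/1.
#' @export
one_hot_mask <- function(mask2d, kind) {
  labs <- kind_labels(kind)
  check_labels_legal(mask2d, kind)
  d <- dim(mask2d)
  out <- array(0, c(d[1], d[2], length(labs)))
  for (k in seq_along(labs)) out[, , k] <- as.numeric(mask2d == labs[k])
  out
}

#' Foreground soft-Dice loss
#'
#' `1 - mean` over non-background classes of the smoothed soft Dice
#' `(2*sum(p*t) + eps) / (sum(p) + sum(t) + eps)`, computed over the whole
#' batch. The epsilon appears in numerator and denominator so that an empty
#' foreground class with near-zero predictions contributes a Dice of 1
#' (loss 0) rather than penalizing absent structures.
#'
#' @param prob softmax probabilities, array (H, W, K, N).
#' @param target one-hot labels of the same shape.
#' @param eps smoothing constant.
#' @return list with `loss` (scalar in \[0, 1\]) and `grad_prob`.
#' @export
foreground_dice_loss <- function(prob, target, eps = 1e-5) {
  d <- dim(prob)
  if (!all(d == dim(target))) stop("prediction/target shape mismatch")
  K <- d[3]
  if (K < 2) stop("need at least one foreground class")
  grad <- array(0, d)
  dice <- numeric(K - 1)
  for (k in 2:K) {
    p <- prob[, , k, , drop = FALSE]
    t <- target[, , k, , drop = FALSE]
    s_pt <- sum(p * t); s_p <- sum(p); s_t <- sum(t)
    den <- s_p + s_t + eps
    dice[k - 1] <- (2 * s_pt + eps) / den
    # d(dice)/dp_i = (2 t_i * den - (2 s_pt + eps)) / den^2 ; loss averages
    # -dice over K-1 classes
    grad[, , k, ] <- -(2 * t * den - (2 * s_pt + eps)) / den^2 / (K - 1)
  }
  list(loss = 1 - mean(dice), grad_prob = grad, dice_per_class = dice)
}

#' Weighted cross-entropy loss
#'
#' Mean over pixels of `-w_c * log(p_c)` at the true class `c`.
#'
#' @param prob softmax probabilities, array (H, W, K, N).
#' @param target one-hot labels of the same shape.
#' @param class_weights positive weight per class, length K.
#' @return list with `loss` and `grad_logits` (gradient directly with
#'   respect to the logits).
#' @export
weighted_cross_entropy <- function(prob, target, class_weights) {
  d <- dim(prob)
  if (!all(d == dim(target))) stop("prediction/target shape mismatch")
  K <- d[3]
  if (length(class_weights) != K) stop("need one weight per class")
  if (any(class_weights <= 0)) stop("class weights must be positive")
  wmap <- array(0, c(d[1], d[2], 1, d[4]))
  for (k in seq_len(K)) wmap <- wmap + class_weights[k] * target[, , k, , drop = FALSE]
  npix <- d[1] * d[2] * d[4]
  p_true <- array(0, c(d[1], d[2], 1, d[4]))
  for (k in seq_len(K)) p_true <- p_true + target[, , k, , drop = FALSE] * prob[, , k, , drop = FALSE]
  loss <- -sum(wmap * log(pmax(p_true, 1e-12))) / npix
  wfull <- array(0, d)
  for (k in seq_len(K)) wfull[, , k, ] <- wmap[, , 1, ]
  grad_logits <- wfull * (prob - target) / npix
  list(loss = loss, grad_logits = grad_logits)
}

# Gradient of loss wrt logits given gradient wrt softmax probabilities.
softmax_backprop <- function(prob, grad_prob) {
  d <- dim(prob)
  inner <- array(0, c(d[1], d[2], 1, d[4]))
  for (k in seq_len(d[3])) inner <- inner + prob[, , k, , drop = FALSE] * grad_prob[, , k, , drop = FALSE]
  g <- array(0, d)
  for (k in seq_len(d[3]))
    g[, , k, ] <- prob[, , k, ] * (grad_prob[, , k, ] - inner[, , 1, ])
  g
}

#' Inverse-frequency class weights
#'
#' Weights proportional to inverse class pixel frequency over a training set,
#' renormalized to mean 1 (the cine "weighted" cross-entropy convention used
#' here). Weights are clipped to `[0.25, 4]` before renormalization: with an
#' unbounded inverse frequency the abundant background class becomes almost
#' free to ignore and the network hallucinates foreground on empty slices.
#'
#' @param masks list of network-grid label matrices.
#' @param kind sequence kind.
#' @param clip lower/upper weight bounds relative to the mean.
#' @return numeric weight vector, one per class.
#' @export
inverse_frequency_weights <- function(masks, kind, clip = c(0.25, 4)) {
  labs <- kind_labels(kind)
  counts <- numeric(length(labs))
  for (m in masks)
    for (k in seq_along(labs)) counts[k] <- counts[k] + sum(m == labs[k])
  counts <- pmax(counts, 1)
  w <- 1 / counts
  w <- w / mean(w)
  w <- pmin(pmax(w, clip[1]), clip[2])
  w / mean(w)
}
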