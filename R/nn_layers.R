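# Layer primitives for the U-Net. Tensors are R arrays dim (H, W, C, N);
# convolution, batch-norm and softmax kernels live in C++ (im2col + BLAS
# gemm), composition and autodiff bookkeeping in R. Batch statistics are
# used in both training and inference (with a single image this reduces to
# instance normalization), which keeps prediction a deterministic function
# of the weights and the input.

bn_fwd <- function(x, gamma, beta, eps = 1e-5) {
  r <- cpp_bn_fwd(x, gamma, beta, eps)
  list(y = r$y, cache = list(xhat = r$xhat, invstd = r$invstd, gamma = gamma))
}

bn_bwd <- function(gy, cache) {
  r <- cpp_bn_bwd(gy, cache$xhat, cache$invstd, cache$gamma)
  list(gx = r$gx, dgamma = r$dgamma, dbeta = r$dbeta)
}

# conv(3x3) -> batch-norm -> ReLU
block_fwd <- function(x, p) {
  z <- cpp_conv2d_fwd(x, p$W, p$b, 3L)
  bn <- bn_fwd(z, p$gamma, p$beta)
  mask <- bn$y > 0
  y <- bn$y * mask
  list(y = y, cache = list(x = x, bn = bn$cache, mask = mask))
}

block_bwd <- function(gy, p, cache) {
  g <- gy * cache$mask
  bb <- bn_bwd(g, cache$bn)
  cb <- cpp_conv2d_bwd(cache$x, p$W, bb$gx, 3L)
  list(gx = cb$gx,
       grads = list(W = cb$gw, b = cb$gb, gamma = bb$dgamma, beta = bb$dbeta))
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Per-pixel softmax over the class axis
#' @param logits array dim (H, W, K, N) or (H, W, K).
#' @return array of the same shape with per-pixel probabilities summing to 1.
#' @export
softmax_map <- function(logits) {
  d <- dim(logits)
  drop3 <- length(d) == 3
  if (drop3) dim(logits) <- c(d, 1L)
  p <- cpp_softmax(logits)
  if (drop3) dim(p) <- d
  p
}
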