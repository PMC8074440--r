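# Sequence-specific 2D U-Net: symmetric encoder (3x3 conv blocks + 2x2 max
# pooling), decoder with 2x2 transposed-convolution upsampling and skip
# connections at every resolution, and a final 1x1 convolution to class
# logits, so the output mask has the resolution of the input image.

#' U-Net configuration
#'
#' @param kind sequence kind; fixes the class count (cine/LGE 4, maps 3,
#'   flow 2).
#' @param depth number of resolution levels including the bottleneck
#'   (must be >= 2).
#' @param base_channels channels at the highest resolution; doubled at each
#'   level down.
#' @param input_shape network grid; inputs are zero-padded internally to a
#'   multiple of `2^(depth - 1)` and the logits cropped back, so the output
#'   mask always matches the input resolution.
#' @return a `unet_config` list.
#' @export
unet_config <- function(kind, depth = 4L, base_channels = 16L,
                        input_shape = c(212L, 212L)) {
  kind <- as_sequence_kind(kind)
  if (depth < 2) stop("depth must be at least 2")
  structure(list(kind = kind, n_classes = kind_n_classes(kind),
                 depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 input_shape = as.integer(input_shape)),
            class = "unet_config")
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

#' Build a U-Net model
#'
#' Weights use He initialization; building twice with the same seed yields
#' identical models (and therefore identical initial predictions).
#'
#' @param cfg a [unet_config].
#' @param seed integer RNG seed for initialization.
#' @return a `unet_model` list with `cfg` and `params`.
#' @export
unet_build <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "unet_config"))
  ch <- cfg$base_channels * 2^(seq_len(cfg$depth) - 1)
  params <- list()
  local_seed(seed, {
    mk_block <- function(cin, cout) list(
      W = he_init(9 * cin, cout, 9 * cin), b = numeric(cout),
      gamma = rep(1, cout), beta = numeric(cout))
    for (d in seq_len(cfg$depth)) {
      cin <- if (d == 1) 1L else ch[d - 1]
      params[[paste0("enc", d, "a")]] <- mk_block(cin, ch[d])
      params[[paste0("enc", d, "b")]] <- mk_block(ch[d], ch[d])
    }
    for (d in rev(seq_len(cfg$depth - 1))) {
      params[[paste0("up", d)]] <- list(
        W = he_init(ch[d + 1], 4 * ch[d], ch[d + 1]), b = numeric(ch[d]))
      params[[paste0("dec", d, "a")]] <- mk_block(2 * ch[d], ch[d])
      params[[paste0("dec", d, "b")]] <- mk_block(ch[d], ch[d])
    }
    params[["head"]] <- list(W = he_init(ch[1], cfg$n_classes, ch[1]),
                             b = numeric(cfg$n_classes))
  })
  structure(list(cfg = cfg, params = params, history = numeric(0)),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p)
    sum(vapply(p, length, integer(1))), numeric(1)))
  cat(sprintf("<unet_model> kind=%s depth=%d base=%d classes=%d params=%d\n",
              x$cfg$kind, x$cfg$depth, x$cfg$base_channels, x$cfg$n_classes,
              np))
  invisible(x)
}

unet_forward <- function(model, x, want_cache = FALSE) {
  p <- model$params
  depth <- model$cfg$depth
  cache <- list()
  skips <- list()
  # pad spatial dims to a multiple of 2^(depth-1) so pooling stays even;
  # the logits are cropped back, keeping output at input resolution
  in_dim <- dim(x)
  div <- 2^(depth - 1)
  pad_dim <- as.integer(ceiling(in_dim[1:2] / div) * div)
  if (any(pad_dim != in_dim[1:2])) {
    xp <- array(0, c(pad_dim, in_dim[3], in_dim[4]))
    xp[seq_len(in_dim[1]), seq_len(in_dim[2]), , ] <- x
    x <- xp
  }
  if (want_cache) cache[["pad"]] <- list(orig = in_dim[1:2], padded = pad_dim)
  cur <- x
  for (d in seq_len(depth)) {
    ba <- block_fwd(cur, p[[paste0("enc", d, "a")]])
    bb <- block_fwd(ba$y, p[[paste0("enc", d, "b")]])
    if (want_cache) { cache[[paste0("enc", d, "a")]] <- ba$cache
                      cache[[paste0("enc", d, "b")]] <- bb$cache }
    cur <- bb$y
    if (d < depth) {
      skips[[d]] <- cur
      pl <- cpp_maxpool_fwd(cur)
      if (want_cache) cache[[paste0("pool", d)]] <-
        list(idx = pl$idx, in_dim = dim(cur))
      cur <- pl$y
    }
  }
  for (d in rev(seq_len(depth - 1))) {
    up <- p[[paste0("up", d)]]
    if (want_cache) cache[[paste0("up", d, "_x")]] <- cur
    u <- cpp_upconv_fwd(cur, up$W, up$b)
    cur <- concat_channels(u, skips[[d]])
    if (want_cache) cache[[paste0("cat", d)]] <-
      c(dim(u)[3], dim(skips[[d]])[3])
    ba <- block_fwd(cur, p[[paste0("dec", d, "a")]])
    bb <- block_fwd(ba$y, p[[paste0("dec", d, "b")]])
    if (want_cache) { cache[[paste0("dec", d, "a")]] <- ba$cache
                      cache[[paste0("dec", d, "b")]] <- bb$cache }
    cur <- bb$y
  }
  if (want_cache) cache[["head_x"]] <- cur
  logits <- cpp_conv2d_fwd(cur, p[["head"]]$W, p[["head"]]$b, 1L)
  if (any(dim(logits)[1:2] != in_dim[1:2]))
    logits <- logits[seq_len(in_dim[1]), seq_len(in_dim[2]), , , drop = FALSE]
  list(logits = logits, cache = cache)
}

unet_backward <- function(model, cache, grad_logits) {
  p <- model$params
  depth <- model$cfg$depth
  grads <- list()
  pad <- cache[["pad"]]
  if (any(pad$padded != pad$orig)) {
    d <- dim(grad_logits)
    gp <- array(0, c(pad$padded, d[3], d[4]))
    gp[seq_len(d[1]), seq_len(d[2]), , ] <- grad_logits
    grad_logits <- gp
  }
  hb <- cpp_conv2d_bwd(cache[["head_x"]], p[["head"]]$W, grad_logits, 1L)
  grads[["head"]] <- list(W = hb$gw, b = hb$gb)
  g <- hb$gx
  gskips <- list()
  for (d in seq_len(depth - 1)) {
    bb <- block_bwd(g, p[[paste0("dec", d, "b")]], cache[[paste0("dec", d, "b")]])
    grads[[paste0("dec", d, "b")]] <- bb$grads
    ba <- block_bwd(bb$gx, p[[paste0("dec", d, "a")]], cache[[paste0("dec", d, "a")]])
    grads[[paste0("dec", d, "a")]] <- ba$grads
    nch <- cache[[paste0("cat", d)]]
    gu <- ba$gx[, , seq_len(nch[1]), , drop = FALSE]
    gskips[[d]] <- ba$gx[, , nch[1] + seq_len(nch[2]), , drop = FALSE]
    ub <- cpp_upconv_bwd(cache[[paste0("up", d, "_x")]],
                         p[[paste0("up", d)]]$W, gu)
    grads[[paste0("up", d)]] <- list(W = ub$gw, b = ub$gb)
    g <- ub$gx
  }
  for (d in rev(seq_len(depth))) {
    if (d < depth) {
      pl <- cache[[paste0("pool", d)]]
      g <- cpp_maxpool_bwd(pl$idx, g, pl$in_dim) + gskips[[d]]
    }
    bb <- block_bwd(g, p[[paste0("enc", d, "b")]], cache[[paste0("enc", d, "b")]])
    grads[[paste0("enc", d, "b")]] <- bb$grads
    ba <- block_bwd(bb$gx, p[[paste0("enc", d, "a")]], cache[[paste0("enc", d, "a")]])
    grads[[paste0("enc", d, "a")]] <- ba$grads
    g <- ba$gx
  }
  grads
}

#' Default desk-scale epoch budget per sequence kind
#'
#' Chosen from training-loss convergence on phantom data: LGE has the lowest
#' tissue contrast (normal myocardium and background are both dark) and
#' converges markedly slower; cine's weighted cross-entropy benefits from a
#' few extra epochs for the thin myocardial ring; the remaining kinds
#' converge quickly.
#'
#' @param kind sequence kind.
#' @return integer epoch count.
#' @export
default_epochs <- function(kind) {
  switch(as_sequence_kind(kind), cine = 10L, lge = 16L, 6L)
}

#' Training configuration
#'
#' Adam with learning rate 0.01, beta1 0.9, beta2 0.999 and batch size 5;
#' the loss is forced by the sequence kind: weighted cross-entropy for cine,
#' foreground soft Dice for every other kind.
#'
#' @param kind sequence kind.
#' @param max_epochs epoch budget (desk-scale default 8).
#' @param batch_size,learning_rate,beta1,beta2 Adam/optimizer settings.
#' @param seed RNG seed controlling shuffling.
#' @return a `train_config` list.
#' @export
train_config <- function(kind, max_epochs = 8L, batch_size = 5L,
                         learning_rate = 0.01, beta1 = 0.9, beta2 = 0.999,
                         seed = 1L) {
  kind <- as_sequence_kind(kind)
  structure(list(kind = kind,
                 loss = if (kind == "cine") "weighted_cross_entropy"
                        else "foreground_dice",
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 seed = as.integer(seed)),
            class = "train_config")
}

adam_step <- function(params, grads, state, lr, b1, b2, t, eps = 1e-8) {
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      g <- grads[[nm]][[f]]
      key <- paste0(nm, ".", f)
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- g * 0; state$v[[key]] <- g * 0
      }
      state$m[[key]] <- b1 * state$m[[key]] + (1 - b1) * g
      state$v[[key]] <- b2 * state$v[[key]] + (1 - b2) * g^2
      mhat <- state$m[[key]] / (1 - b1^t)
      vhat <- state$v[[key]] / (1 - b2^t)
      params[[nm]][[f]] <- params[[nm]][[f]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

batch_tensors <- function(images, masks, idx, kind) {
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  K <- kind_n_classes(kind)
  n <- length(idx)
  x <- array(0, c(H, W, 1, n))
  t <- array(0, c(H, W, K, n))
  for (i in seq_len(n)) {
    x[, , 1, i] <- images[[idx[i]]]
    t[, , , i] <- one_hot_mask(masks[[idx[i]]], kind)
  }
  list(x = x, t = t)
}

train_batch_loss <- function(model, x, t, cfg, class_weights) {
  fwd <- unet_forward(model, x, want_cache = TRUE)
  prob <- softmax_map(fwd$logits)
  if (cfg$loss == "weighted_cross_entropy") {
    l <- weighted_cross_entropy(prob, t, class_weights)
    gl <- l$grad_logits
  } else {
    l <- foreground_dice_loss(prob, t)
    gl <- softmax_backprop(prob, l$grad_prob)
  }
  list(loss = l$loss, grads = unet_backward(model, fwd$cache, gl))
}

#' Train a U-Net on 2D slices
#'
#' @param model a [unet_build()] model.
#' @param images list of network-grid image matrices.
#' @param masks list of matching integer label matrices.
#' @param cfg a [train_config] whose kind matches the model's.
#' @param class_weights optional per-class weights for the cine loss;
#'   computed from the training masks by [inverse_frequency_weights()] when
#'   omitted.
#' @param verbose print per-epoch mean loss.
#' @return the trained model; `model$history` holds the per-epoch mean loss.
#' @export
train_unet <- function(model, images, masks, cfg, class_weights = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"), inherits(cfg, "train_config"))
  if (cfg$kind != model$cfg$kind)
    stop("training config kind does not match the model kind")
  if (length(images) == 0) stop("empty training set")
  if (length(images) != length(masks)) stop("images/masks length mismatch")
  if (cfg$loss == "weighted_cross_entropy" && is.null(class_weights))
    class_weights <- inverse_frequency_weights(masks, cfg$kind)
  params <- model$params
  state <- list(m = list(), v = list())
  t_step <- 0
  history <- numeric(cfg$max_epochs)
  local_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(length(images))
      losses <- c()
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
        bt <- batch_tensors(images, masks, idx, cfg$kind)
        model$params <- params
        res <- train_batch_loss(model, bt$x, bt$t, cfg, class_weights)
        t_step <- t_step + 1
        upd <- adam_step(params, res$grads, state, cfg$learning_rate,
                         cfg$beta1, cfg$beta2, t_step)
        params <- upd$params; state <- upd$state
        losses <- c(losses, res$loss)
      }
      history[epoch] <- mean(losses)
      if (verbose)
        message(sprintf("epoch %d/%d: loss %.4f", epoch, cfg$max_epochs,
                        history[epoch]))
    }
  })
  model$params <- params
  model$history <- c(model$history, history)
  model
}

#' Predict the softmax map for one network-grid slice
#'
#' @param model a trained `unet_model`.
#' @param image numeric matrix on the model's input grid.
#' @return array (H, W, n_classes) of per-pixel class probabilities.
#' @export
predict_slice <- function(model, image) {
  stopifnot(inherits(model, "unet_model"))
  if (is.null(dim(image)) || !all(dim(image) == model$cfg$input_shape))
    stop(sprintf("input must be %s",
                 paste(model$cfg$input_shape, collapse = "x")))
  x <- array(image, c(dim(image), 1L, 1L))
  logits <- unet_forward(model, x)$logits
  p <- softmax_map(logits)
  array(p, dim(p)[1:3])
}

#' Save / load a model checkpoint
#'
#' Checkpoints are plain-text JSON (weights flattened with their shapes) plus
#' the configuration, so they survive text-only archiving.
#'
#' @param model a `unet_model`.
#' @param path output file.
#' @export
save_model <- function(model, path) {
  ser <- list(cfg = unclass(model$cfg),
              history = model$history,
              params = lapply(model$params, function(p)
                lapply(p, function(a)
                  list(dim = if (is.matrix(a)) dim(a) else length(a),
                       data = as.numeric(a)))))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- unet_config(ser$cfg$kind, ser$cfg$depth, ser$cfg$base_channels,
                     ser$cfg$input_shape)
  params <- lapply(ser$params, function(p)
    lapply(p, function(a) {
      if (length(a$dim) == 2) matrix(a$data, a$dim[1], a$dim[2]) else a$data
    }))
  structure(list(cfg = cfg, params = params,
                 history = as.numeric(ser$history)),
            class = "unet_model")
}
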