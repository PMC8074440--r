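test_that("the model emits a valid softmax at input resolution", {
  cfg <- unet_config("cine", depth = 4, base_channels = 4)
  model <- unet_build(cfg, seed = 1)
  set.seed(1)
  img <- matrix(rnorm(212 * 212), 212, 212)
  p <- predict_slice(model, img)
  expect_equal(dim(p), c(212, 212, 4))
  expect_true(all(p >= 0))
  expect_true(all(abs(apply(p, c(1, 2), sum) - 1) < 1e-5))
  expect_error(predict_slice(model, matrix(0, 64, 64)), "212")
})

test_that("configuration constraints are enforced", {
  expect_error(unet_config("cine", depth = 1), "at least 2")
  expect_equal(unet_config("flow")$n_classes, 2L)
  expect_equal(unet_config("t1_post")$n_classes, 3L)
})

test_that("model building and prediction are deterministic in the seed", {
  cfg <- unet_config("t2", depth = 3, base_channels = 4,
                     input_shape = c(32L, 32L))
  m1 <- unet_build(cfg, seed = 7)
  m2 <- unet_build(cfg, seed = 7)
  expect_identical(m1$params, m2$params)
  img <- matrix(seq_len(32 * 32) / 500, 32, 32)
  expect_identical(predict_slice(m1, img), predict_slice(m2, img))
  m3 <- unet_build(cfg, seed = 8)
  expect_false(identical(m1$params$enc1a$W, m3$params$enc1a$W))
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- unet_config("t2", depth = 2, base_channels = 3,
                     input_shape = c(8L, 8L))
  model <- unet_build(cfg, seed = 2)
  set.seed(5)
  x <- array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  t <- array(0, c(8, 8, 3, 2))
  cls <- sample(1:3, 8 * 8 * 2, TRUE)
  for (i in seq_along(cls)) {
    ix <- arrayInd(i, c(8, 8, 2)); t[ix[1], ix[2], cls[i], ix[3]] <- 1
  }
  fwd <- cmrpipe:::unet_forward(model, x, want_cache = TRUE)
  prob <- softmax_map(fwd$logits)
  l <- foreground_dice_loss(prob, t)
  gl <- cmrpipe:::softmax_backprop(prob, l$grad_prob)
  grads <- cmrpipe:::unet_backward(model, fwd$cache, gl)
  loss_at <- function(m) {
    f <- cmrpipe:::unet_forward(m, x)
    foreground_dice_loss(softmax_map(f$logits), t)$loss
  }
  eps <- 1e-5
  set.seed(6)
  for (nm in c("enc1a", "enc2b", "up1", "dec1b", "head")) {
    for (fld in setdiff(names(model$params[[nm]]), "b")) {
      i <- sample(length(model$params[[nm]][[fld]]), 1)
      mp <- model; mp$params[[nm]][[fld]][i] <- mp$params[[nm]][[fld]][i] + eps
      mm <- model; mm$params[[nm]][[fld]][i] <- mm$params[[nm]][[fld]][i] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      ana <- grads[[nm]][[fld]][i]
      expect_lt(abs(num - ana) / max(1e-7, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("training rejects invalid inputs and lowers the loss", {
  cfg <- unet_config("t2", depth = 2, base_channels = 4,
                     input_shape = c(16L, 16L))
  model <- unet_build(cfg, seed = 3)
  expect_error(train_unet(model, list(), list(), train_config("t2")),
               "empty")
  expect_error(train_unet(model, list(matrix(0, 16, 16)),
                          list(matrix(0L, 16, 16)), train_config("cine")),
               "kind")
  # small synthetic disks: loss decreases over epochs
  set.seed(9)
  imgs <- list(); msks <- list()
  for (i in 1:10) {
    m <- matrix(0L, 16, 16)
    ctr <- runif(2, 6, 10)
    for (r in 1:16) for (c in 1:16)
      if ((r - ctr[1])^2 + (c - ctr[2])^2 <= 9) m[r, c] <- 1L
    img <- m * 2 + matrix(rnorm(256, 0, 0.3), 16, 16)
    imgs[[i]] <- (img - mean(img)) / sd(as.vector(img))
    msks[[i]] <- m
  }
  trained <- train_unet(model, imgs, msks,
                        train_config("t2", max_epochs = 4, seed = 1))
  expect_lt(trained$history[4], trained$history[1])
})

test_that("checkpoints round-trip through the JSON format", {
  cfg <- unet_config("flow", depth = 2, base_channels = 3,
                     input_shape = c(16L, 16L))
  model <- unet_build(cfg, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  m2 <- load_model(path)
  expect_equal(m2$params, model$params, tolerance = 1e-12)
  img <- matrix(rnorm(256), 16, 16)
  expect_equal(predict_slice(m2, img), predict_slice(model, img),
               tolerance = 1e-12)
})
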