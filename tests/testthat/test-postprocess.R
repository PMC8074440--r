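test_that("argmax labeling maps classes to codebook labels with tie-break", {
  sm <- array(0, c(2, 2, 3))
  sm[1, 1, ] <- c(0.1, 0.8, 0.1)
  sm[1, 2, ] <- c(0.5, 0.5, 0.0)   # tie -> lowest class index (background)
  sm[2, 1, ] <- c(0.2, 0.3, 0.5)
  sm[2, 2, ] <- c(1, 0, 0)
  lab <- argmax_labels(sm, "t2")
  expect_identical(lab, matrix(c(1L, 2L, 0L, 0L), 2, 2))
  # one-hot maps reproduce their labels
  oh <- one_hot_mask(lab, "t2")
  expect_identical(argmax_labels(oh, "t2"), lab)
  expect_error(argmax_labels(array(0, c(2, 2, 5)), "t2"), "class count")
})

test_that("stacking per-slice labels reconstructs the 3D mask", {
  ph <- make_phantom(tiny_spec("t1_native", noise_sd = 0, seed = 11))
  pp <- cmrpipe:::preprocess_stack(ph$image, target_shape = c(32L, 32L),
                                   target_spacing_mm = 1.37)
  # feed the ground-truth labels through the stacking path (spatial identity
  # here, so the phantom mask must reconstruct exactly)
  labels_list <- lapply(seq_len(n_slices(ph$image)), function(s)
    ph$truth$mask$labels[, , s])
  out <- stack_to_3d(labels_list, pp$records, "t1_native",
                     n_slices = n_slices(ph$image), n_frames = 1L,
                     in_plane_spacing_mm = 1.37, slice_thickness_mm = 8)
  expect_identical(out$labels, ph$truth$mask$labels)
  expect_error(stack_to_3d(labels_list[-1], pp$records, "t1_native",
                           n_slices(ph$image), 1L, 1.37, 8),
               "one label map per slice")
})

test_that("largest_component removes satellites and honors the tie rule", {
  arr <- array(0L, c(8, 8, 3))
  arr[2:5, 2:5, 1:2] <- 1L   # 32-voxel blob
  arr[8, 8, 3] <- 1L         # isolated voxel
  m <- cmr_mask(arr, "t2", 1, 8)
  out <- largest_component(m, 1L)
  expect_equal(sum(out$labels == 1L), 32)
  expect_equal(out$labels[8, 8, 3], 0L)
  # single blob unchanged
  expect_identical(largest_component(out, 1L)$labels, out$labels)
  # voxel count never increases
  expect_lte(sum(out$labels == 1L), sum(arr == 1L))

  # two equal blobs: the one whose minimum (slice,row,col) is smallest wins
  tie <- array(0L, c(6, 6, 2))
  tie[1:2, 1:2, 2] <- 1L           # slice 2
  tie[5:6, 5:6, 1] <- 1L           # slice 1 -> lexicographically first
  mt <- largest_component(cmr_mask(tie, "t2", 1, 8), 1L)
  expect_equal(sum(mt$labels[, , 1] == 1L), 4)
  expect_equal(sum(mt$labels[, , 2] == 1L), 0)
})

test_that("convexify fills notches and closes myocardial gaps", {
  disk <- array(0L, c(32, 32, 1))
  for (r in 1:32) for (c in 1:32)
    if ((r - 16)^2 + (c - 16)^2 <= 64) disk[r, c, 1] <- 1L
  m <- cmr_mask(disk, "t2", 1, 8)
  expect_identical(convexify(m)$labels, disk)  # hull idempotence on a disk

  notched <- disk
  notched[15:17, 16:21, 1] <- 0L  # interior notch, hull vertices untouched
  mn <- convexify(cmr_mask(notched, "t2", 1, 8))
  expect_gt(sum(mn$labels == 1L), sum(notched == 1L))  # notch filled
  expect_true(all(mn$labels[disk == 1L] == 1L))        # superset property

  # annulus with a radial gap: the myocardial ring is closed
  ring2d <- matrix(0L, 32, 32)
  for (r in 1:32) for (c in 1:32) {
    d2 <- (r - 16)^2 + (c - 16)^2
    if (d2 <= 36) ring2d[r, c] <- 1L
    else if (d2 <= 100) ring2d[r, c] <- 2L
  }
  gap2d <- ring2d
  gap2d[abs(row(gap2d) - 16) <= 2 & col(gap2d) > 16 & ring2d == 2L] <- 0L
  mg <- convexify(cmr_mask(array(gap2d, c(32, 32, 1)), "t2", 1, 8))
  # every interior ring pixel (strictly inside the epicardial hull) is
  # restored; only hull-vertex pixels removed by the gap may stay out
  interior <- matrix(FALSE, 32, 32)
  for (r in 1:32) for (c in 1:32)
    if ((r - 16)^2 + (c - 16)^2 <= 81) interior[r, c] <- TRUE
  expect_true(all(mg$labels[array(ring2d == 2L & interior, c(32, 32, 1))] == 2L))
  expect_true(all(mg$labels[array(ring2d == 1L, c(32, 32, 1))] == 1L))
  expect_gt(sum(mg$labels == 2L), sum(gap2d == 2L))
})

test_that("convexify never shrinks cavity or aorta areas", {
  ph <- make_phantom(tiny_spec("lge", seed = 12))
  m <- ph$truth$mask
  out <- convexify(m)
  for (s in seq_len(n_slices(m))) {
    expect_gte(sum(out$labels[, , s] == 1L), sum(m$labels[, , s] == 1L))
  }
  fl <- make_flow_phantom(tiny_spec("flow", seed = 12))
  fo <- convexify(fl$truth$mask)
  expect_gte(sum(fo$labels == 5L), sum(fl$truth$mask$labels == 5L))
})

test_that("pipeline steps are idempotent on their own output", {
  ph <- make_phantom(tiny_spec("t1_native", seed = 13))
  m <- ph$truth$mask
  m1 <- largest_component(m, 1L)
  expect_identical(largest_component(m1, 1L)$labels, m1$labels)
  c1 <- convexify(m1)
  expect_identical(convexify(c1)$labels, c1$labels)
})

test_that("slice features match their definitions", {
  sm <- softmax_from_mask(matrix(2L, 4, 4), "t2", confidence = 1)
  img <- matrix(0.5, 4, 4)
  f <- extract_slice_features(sm, img, 1, 11, "t2")
  expect_equal(f$mean_softmax_myo, 1.0)
  expect_equal(f$mean_intensity_myo, 0.5)
  expect_equal(f$norm_slice_pos, 0.0)
  f2 <- extract_slice_features(sm, img, 11, 11, "t2")
  expect_equal(f2$norm_slice_pos, 1.0)
  # no predicted myocardium -> NULL (auto-discard upstream)
  sm0 <- softmax_from_mask(matrix(0L, 4, 4), "t2", confidence = 0.9)
  expect_null(extract_slice_features(sm0, img, 2, 11, "t2"))
})

test_that("myocardium intensity feature is the z-scored tissue mean", {
  sp <- tiny_spec("t2", noise_sd = 0, seed = 14)
  ph <- make_phantom(sp)
  s <- 3
  sl <- ph$image$voxels[, , s]
  ng <- to_network_grid(sl, sp$in_plane_spacing_mm, target_shape = sp$grid,
                        target_spacing_mm = sp$in_plane_spacing_mm)
  sm <- softmax_from_mask(ph$truth$mask$labels[, , s], "t2", 0.95)
  f <- extract_slice_features(sm, ng$image, s, sp$n_slices, "t2")
  z_expected <- (sp$tissue_means[["lv_myo"]] - mean(sl)) / sd(as.vector(sl))
  expect_equal(f$mean_intensity_myo, unname(z_expected), tolerance = 1e-9)
})

test_that("the rejector separates linearly separable features perfectly", {
  set.seed(20)
  feats <- data.frame(
    mean_softmax_myo = c(runif(40, 0.8, 1), runif(40, 0.2, 0.5)),
    mean_intensity_myo = rnorm(80),
    norm_slice_pos = runif(80),
    discard = rep(c(FALSE, TRUE), each = 40))
  rej <- train_slice_rejector(feats, rf_config(seed = 1))
  expect_equal(rej$train_accuracy, 1.0)
  expect_error(train_slice_rejector(feats[feats$discard, ], rf_config()),
               "both keep and discard")
})

test_that("shuffled labels yield chance-level held-out accuracy", {
  set.seed(21)
  n <- 60
  accs <- replicate(100, {
    feats <- data.frame(
      mean_softmax_myo = runif(n), mean_intensity_myo = rnorm(n),
      norm_slice_pos = runif(n),
      discard = sample(rep(c(TRUE, FALSE), n / 2)))
    train <- feats[1:(n / 2), ]; test <- feats[(n / 2 + 1):n, ]
    if (length(unique(train$discard)) < 2) return(NA)
    rej <- train_slice_rejector(train, rf_config(seed = 1))
    mean(predict_rejector(rej, test) == test$discard)
  })
  expect_equal(mean(accs, na.rm = TRUE), 0.5, tolerance = 0.05)
})

test_that("an oracle rejector restores Dice 1 on a one-extra-slice fixture", {
  corpus <- make_rejection_corpus("t1_native", n_stacks = 1, seed = 30,
                                  n_extra_range = c(1L, 1L))
  case <- corpus[[1]]
  expect_lt(dice3d(case$corrupted, case$truth$mask, 1L), 1)
  # oracle: discard exactly the slices that are empty in the truth
  oracle <- structure(list(), class = "slice_rejector_oracle")
  fixed <- case$corrupted
  for (s in seq_len(n_slices(fixed)))
    if (sum(case$truth$mask$labels[, , s]) == 0) fixed$labels[, , s] <- 0L
  expect_equal(dice3d(fixed, case$truth$mask, 1L), 1)
  expect_equal(dice3d(fixed, case$truth$mask, 2L), 1)
})

test_that("a rejector that discards nothing is the identity", {
  corpus <- make_rejection_corpus("t2", n_stacks = 8, seed = 31)
  feats <- rejection_features(corpus)
  keep_all <- feats
  keep_all$discard[1] <- TRUE  # need both classes; forest still learns "keep"
  rej <- train_slice_rejector(keep_all, rf_config(seed = 2))
  case <- corpus[[3]]
  out <- apply_slice_rejector(case$corrupted, rej, case$softmax_list,
                              case$images_list)
  # every slice kept by this near-trivial forest stays identical
  kept <- which(vapply(seq_len(n_slices(out)), function(s)
    sum(out$labels[, , s]) > 0, logical(1)))
  for (s in kept)
    expect_identical(out$labels[, , s], case$corrupted$labels[, , s])
  # NULL rejector is exactly the identity
  expect_identical(
    apply_slice_rejector(case$corrupted, NULL, case$softmax_list,
                         case$images_list)$labels,
    case$corrupted$labels)
})

test_that("slice rejection refuses cine and flow masks", {
  ph <- make_phantom(tiny_spec("cine", seed = 32))
  expect_error(apply_slice_rejector(ph$truth$mask, NULL, list(), list()),
               "does not apply")
})

test_that("trained rejector recovers most over-segmented slices", {
  corpus <- make_rejection_corpus("t1_native", n_stacks = 40, seed = 33)
  train <- corpus[1:25]; test <- corpus[26:40]
  rej <- train_slice_rejector(rejection_features(train), rf_config(seed = 3))
  feats <- rejection_features(test)
  pred <- predict_rejector(rej, feats)
  recall <- sum(pred & feats$discard) / sum(feats$discard)
  expect_gte(recall, 0.9)
})
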