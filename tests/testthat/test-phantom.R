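test_that("phantom output is a pure function of spec and seed", {
  sp <- tiny_spec("lge", seed = 42)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$truth$mask$labels, b$truth$mask$labels)
  c2 <- make_phantom(tiny_spec("lge", seed = 43))
  expect_false(identical(a$image$voxels, c2$image$voxels))
})

test_that("zero-noise phantoms carry exact tissue means", {
  ph <- make_phantom(tiny_spec("lge", noise_sd = 0, seed = 1))
  tm <- ph$truth$spec$tissue_means
  scar <- ph$truth$mask$labels == LABELS[["scar"]]
  expect_true(any(scar))
  expect_true(all(ph$image$voxels[scar] == tm[["scar"]]))
  myo <- ph$truth$mask$labels == LABELS[["lv_myo"]]
  expect_true(all(ph$image$voxels[myo] == tm[["lv_myo"]]))
})

test_that("truth volumes equal voxel counts times voxel volume exactly", {
  ph <- make_phantom(tiny_spec("cine", seed = 5))
  vv <- voxel_volume_mm3(ph$truth$mask)
  for (f in c(1, 3)) {
    m <- ph$truth$mask$labels[, , , f]
    expect_identical(ph$truth$volumes_ml$lv_cavity[f],
                     sum(m == 1L) * vv / 1000)
    expect_identical(ph$truth$volumes_ml$rv_cavity[f],
                     sum(m == 3L) * vv / 1000)
  }
  v <- ph$truth$volumes_ml$lv_cavity
  ef <- 100 * (max(v) - min(v)) / max(v)
  expect_equal(ph$truth$true_lv_ef_pct, ef, tolerance = 1e-9)
  expect_equal(ph$truth$ed_frame, which.max(v))
  expect_equal(ph$truth$es_frame, which.min(v))
})

test_that("radius schedule has a unique ED and ES frame", {
  sp <- phantom_spec("cine", seed = 1)
  rs <- cmrpipe:::radius_schedule(sp)
  expect_equal(which.max(rs), 1L)
  expect_equal(sum(rs == max(rs)), 1L)
  expect_equal(sum(rs == min(rs)), 1L)
})

test_that("a radius schedule solved for 100/40 mL gives EF near 60", {
  sp <- phantom_spec("cine", grid = c(96L, 96L), seed = 2)
  r_ed <- lv_radius_for_volume(100, sp)
  r_es <- lv_radius_for_volume(40, sp)
  sp2 <- phantom_spec("cine", grid = c(96L, 96L),
                      lv_radius_ed_mm = r_ed, lv_radius_es_mm = r_es, seed = 2)
  # analytic disk-summation volumes invert exactly
  tf2 <- sum(cmrpipe:::taper_factors(sp2)^2)
  expect_equal(pi * r_ed^2 * tf2 * sp2$slice_thickness_mm / 1000, 100,
               tolerance = 1e-12)
  ph <- make_phantom(sp2)
  # voxelized EF deviates from 60 only through partial-volume discretization
  expect_equal(ph$truth$true_lv_ef_pct, 60, tolerance = 2 / 60)
  expect_equal(max(ph$truth$volumes_ml$lv_cavity), 100, tolerance = 0.05)
})

test_that("phantom geometry errors when myocardium vanishes", {
  expect_error(make_phantom(tiny_spec("t2", myo_thickness_mm = 0.05,
                                      lv_radius_ed_mm = 0.4, seed = 1)))
})

test_that("over-segmentation fixture adds exactly the requested slices", {
  sp <- tiny_spec("t1_native", seed = 9)
  fx0 <- make_oversegmentation_fixture(sp, 0)
  expect_identical(fx0$corrupted$labels, fx0$truth$mask$labels)

  fx1 <- make_oversegmentation_fixture(sp, 1)
  diff_slices <- which(vapply(seq_len(n_slices(fx1$corrupted)), function(s)
    sum(fx1$corrupted$labels[, , s]) > 0 &&
      sum(fx1$truth$mask$labels[, , s]) == 0, logical(1)))
  expect_length(diff_slices, 1)
  expect_lt(dice3d(fx1$corrupted, fx1$truth$mask, LABELS[["lv_cavity"]]), 1)
  fixed <- fx1$corrupted
  fixed$labels[, , diff_slices] <- 0L
  expect_equal(dice3d(fixed, fx1$truth$mask, LABELS[["lv_cavity"]]), 1)
  expect_equal(dice3d(fixed, fx1$truth$mask, LABELS[["lv_myo"]]), 1)

  expect_error(make_oversegmentation_fixture(sp, 99), "exceeds")
})

test_that("flow truth follows v*A*T for a constant velocity field", {
  # 10 cm/s over 4 cm^2 for 1 s -> 40 mL
  vel <- array(0, c(10, 10, 1, 4))
  lab <- array(0L, c(10, 10, 1, 4))
  lab[1:5, 1:8, 1, ] <- 5L  # 40 pixels of 10 mm^2 = 4 cm^2
  vel[lab == 5L] <- 10
  stack <- cmr_stack(vel, "flow", sqrt(10), 10, frame_duration_ms = 250)
  mask <- cmr_mask(lab, "flow", sqrt(10), 10, frame_duration_ms = 250)
  fl <- flow_amplitudes(stack, mask)
  expect_equal(fl$net_flow_ml, 40, tolerance = 1e-9)
  expect_equal(fl$backward_flow_ml, 0)

  stack$voxels <- -stack$voxels
  fl2 <- flow_amplitudes(stack, mask)
  expect_equal(fl2$net_flow_ml, -40, tolerance = 1e-9)
  expect_equal(fl2$backward_flow_ml, 40, tolerance = 1e-9)
})

test_that("voxelized sinusoidal flow matches the analytic integral within 2%", {
  sp <- phantom_spec("flow", seed = 4)
  ph <- make_flow_phantom(sp)
  # spatial integral of the parabolic profile: v_peak * pi R^2 / 2; the
  # sinusoid sums to zero over a full cycle, leaving offset * T
  t_s <- 0.8
  analytic_net <- (sp$v_peak_cm_s * 10) * pi * sp$aorta_radius_mm^2 / 2 *
    sp$flow_offset * t_s / 1000
  expect_equal(ph$truth$true_net_flow_ml, analytic_net,
               tolerance = 0.02)
  expect_gt(ph$truth$true_backward_flow_ml, 0)
})

test_that("sampled phantom specs vary but remain deterministic in the seed", {
  a <- sample_phantom_spec("t2", seed = 10)
  b <- sample_phantom_spec("t2", seed = 10)
  c2 <- sample_phantom_spec("t2", seed = 11)
  expect_identical(a$lv_radius_ed_mm, b$lv_radius_ed_mm)
  expect_false(identical(a$lv_radius_ed_mm, c2$lv_radius_ed_mm))
})
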