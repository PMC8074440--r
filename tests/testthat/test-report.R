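phantom_ranges <- function() {
  # ranges matched to the desk-scale phantom geometry (the shipped clinical
  # defaults are deliberately overridable per study)
  list(lv_ef_pct = c(20, 80), rv_ef_pct = c(20, 80),
       lv_edv_ml = c(10, 200), lv_esv_ml = c(2, 150), lv_sv_ml = c(5, 120),
       lv_mass_g = c(10, 200), rv_edv_ml = c(5, 200), rv_esv_ml = c(1, 150),
       rv_sv_ml = c(2, 120), scar_pct = c(0, 60),
       mean_t1_ms = c(800, 1500), mean_t1post_ms = c(250, 750),
       mean_t2_ms = c(30, 90), net_flow_ml = c(20, 150),
       backward_flow_ml = c(0, 60))
}

make_study_dir <- function(dir, n = 3, kinds = c("cine", "lge"), corrupt = NULL) {
  rows <- list()
  for (i in seq_len(n)) for (k in kinds) {
    sp <- sample_phantom_spec(k, seed = 7000 + 13 * i + match(k, SEQUENCE_KINDS))
    ph <- make_phantom(sp)
    mask <- ph$truth$mask
    if (!is.null(corrupt) && corrupt$subject == i && corrupt$kind == k) {
      # flatten the cavity cycle so EF collapses below the plausible range
      ed <- ph$truth$ed_frame
      for (f in seq_len(n_frames(mask))) mask$labels[, , , f] <- mask$labels[, , , ed]
      mask$labels[1, 1, 1, seq(2, n_frames(mask))] <- 1L
      mask$labels[2, 1, 1, 2] <- 1L  # ES barely below EDV -> EF ~ 0
    }
    ipath <- file.path(dir, sprintf("s%d_%s_img.nii.gz", i, k))
    mpath <- file.path(dir, sprintf("s%d_%s_mask.nii.gz", i, k))
    write_stack(ph$image, ipath)
    write_mask(mask, mpath)
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = sprintf("subj%02d", i), kind = k,
      image_path = ipath, mask_path = mpath)
  }
  manifest <- file.path(dir, "study.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  manifest
}

test_that("in-range phantom studies produce zero flags", {
  dir <- withr::local_tempdir()
  manifest <- make_study_dir(dir, n = 3)
  rep <- run_study(manifest, ranges = phantom_ranges())
  expect_equal(nrow(rep$failures), 0)
  expect_equal(nrow(rep$flags), 0)
  expect_equal(length(unique(rep$params$subject_id)), 3)
  expect_true(all(c("lv_ef_pct", "scar_pct") %in% rep$params$parameter))
})

test_that("a corrupted subject is flagged exactly on its broken parameter", {
  dir <- withr::local_tempdir()
  manifest <- make_study_dir(dir, n = 3,
                             corrupt = list(subject = 2, kind = "cine"))
  rep <- run_study(manifest, ranges = phantom_ranges())
  expect_true("subj02" %in% rep$flags$subject_id)
  expect_true("lv_ef_pct" %in% rep$flags$parameter[rep$flags$subject_id == "subj02"])
  expect_false("subj01" %in% rep$flags$subject_id)
})

test_that("study reruns are byte-identical and failures skip, not abort", {
  dir <- withr::local_tempdir()
  manifest <- make_study_dir(dir, n = 2)
  m <- read_manifest(manifest)
  m$image_path[1] <- file.path(dir, "missing.nii.gz")
  out1 <- file.path(dir, "out1"); out2 <- file.path(dir, "out2")
  r1 <- run_study(m, ranges = phantom_ranges(), out_dir = out1)
  r2 <- run_study(m, ranges = phantom_ranges(), out_dir = out2)
  expect_equal(nrow(r1$failures), 1)
  expect_gt(nrow(r1$params), 0)
  expect_identical(readLines(file.path(out1, "report.csv")),
                   readLines(file.path(out2, "report.csv")))
})

test_that("confidence reproduces agreement on paired study reports", {
  params <- data.frame(
    subject_id = rep(sprintf("s%d", 1:4), 2),
    kind = "cine",
    parameter = rep(c("lv_ef_pct", "lv_sv_ml"), each = 4),
    value = c(60, 40, 70, 55, 80, 90, 100, 110))
  ref <- params
  ref$value <- c(58, 44, 69, 51, 80, 90, 100, 110)
  cf <- confidence(params, ref)
  ef <- cf[cf$parameter == "lv_ef_pct", ]
  expect_equal(ef$mean_error, 2.75)          # absolute rule
  expect_equal(ef$bias, mean(c(2, -4, 1, 4)))
  sv <- cf[cf$parameter == "lv_sv_ml", ]
  expect_equal(sv$pearson_r, 1)
  expect_equal(sv$mean_error, 0)             # relative rule, identical values

  pert <- ref
  set.seed(1); pert$value <- pert$value + rnorm(8)
  cf2 <- confidence(params, pert)
  expect_true(all(cf2$pearson_r < 1))
})

test_that("physiological ranges validate their bounds", {
  ranges <- default_physio_ranges()
  expect_true(all(vapply(ranges, function(b) b[1] < b[2], logical(1))))
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("lv_ef_pct: [80, 20]", bad)
  expect_error(read_physio_ranges(bad), "low < high")
})
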