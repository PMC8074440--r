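# Over-segmentation corpus for training and evaluating the RF slice
# rejector. Each case pairs a ground-truth phantom with a corrupted mask
# carrying spurious basal slices, plus emulated per-slice softmax maps: the
# emulated network is confident on true cardiac slices and less confident on
# the non-cardiac tissue it over-segmented, mirroring the behavior the
# rejector exploits in a real pipeline.

#' Softmax map consistent with a label map
#'
#' Assigns probability `confidence` to each pixel's labeled class and spreads
#' the remainder uniformly over the other classes.
#'
#' @param mask2d integer label matrix.
#' @param kind sequence kind.
#' @param confidence scalar in (1/K, 1].
#' @return array (H, W, K).
#' @export
softmax_from_mask <- function(mask2d, kind, confidence = 0.95) {
  labs <- kind_labels(kind)
  K <- length(labs)
  stopifnot(confidence > 1 / K, confidence <= 1)
  oh <- one_hot_mask(mask2d, kind)
  oh * confidence + (1 - oh) * (1 - confidence) / (K - 1)
}

#' Generate an over-segmentation corpus
#'
#' Randomized phantoms of a static kind, each corrupted with 1-2 spurious
#' basal slices (see [make_oversegmentation_fixture()]). Emulated softmax
#' confidence is drawn from `conf_true` on genuinely cardiac slices and from
#' the lower `conf_fake` range on over-segmented ones.
#'
#' @param kind lge or a map kind.
#' @param n_stacks corpus size.
#' @param seed integer seed.
#' @param n_extra_range range of spurious slice counts per stack.
#' @param conf_true,conf_fake softmax confidence ranges.
#' @return list of cases, each with `image`, `truth`, `corrupted`,
#'   `softmax_list`, `images_list` (network-grid z-scored slices) and
#'   `n_extra`.
#' @export
make_rejection_corpus <- function(kind, n_stacks = 100L, seed = 1L,
                                  n_extra_range = c(1L, 2L),
                                  conf_true = c(0.85, 0.99),
                                  conf_fake = c(0.55, 0.80)) {
  kind <- as_sequence_kind(kind)
  stopifnot(!kind %in% c("cine", "flow"))
  local_seed(seed, {
    lapply(seq_len(n_stacks), function(i) {
      sp <- sample_phantom_spec(kind, seed = sample.int(2^31 - 2, 1))
      n_extra <- sample(seq(n_extra_range[1], n_extra_range[2]), 1)
      fx <- make_oversegmentation_fixture(sp, n_extra)
      ns <- n_slices(fx$corrupted)
      stats <- list(mean = mean(fx$image$voxels),
                    sd = sd(as.vector(fx$image$voxels)))
      softmax_list <- vector("list", ns)
      images_list <- vector("list", ns)
      for (s in seq_len(ns)) {
        truth_empty <- sum(fx$truth$mask$labels[, , s]) == 0
        has_seg <- sum(fx$corrupted$labels[, , s]) > 0
        conf <- if (has_seg && truth_empty) runif(1, conf_fake[1], conf_fake[2])
                else runif(1, conf_true[1], conf_true[2])
        softmax_list[[s]] <- softmax_from_mask(fx$corrupted$labels[, , s],
                                               kind, conf)
        ng <- to_network_grid(fx$image$voxels[, , s], sp$in_plane_spacing_mm,
                              target_shape = sp$grid,
                              target_spacing_mm = sp$in_plane_spacing_mm,
                              norm_stats = stats)
        images_list[[s]] <- ng$image
      }
      list(image = fx$image, truth = fx$truth, corrupted = fx$corrupted,
           softmax_list = softmax_list, images_list = images_list,
           n_extra = fx$n_extra)
    })
  })
}

#' Slice features and discard labels for a rejection corpus
#'
#' A slice is a discard example when the corrupted mask segments myocardium
#' on it but the ground truth is empty there.
#'
#' @param corpus output of [make_rejection_corpus()].
#' @return data.frame of feature rows with `discard` and `case` columns.
#' @export
rejection_features <- function(corpus) {
  rows <- list()
  for (i in seq_along(corpus)) {
    case <- corpus[[i]]
    ns <- n_slices(case$corrupted)
    for (s in seq_len(ns)) {
      if (sum(case$corrupted$labels[, , s]) == 0) next
      feat <- extract_slice_features(case$softmax_list[[s]],
                                     case$images_list[[s]], s, ns,
                                     case$corrupted$kind)
      if (is.null(feat)) next
      feat$discard <- sum(case$truth$mask$labels[, , s]) == 0
      feat$case <- i
      rows[[length(rows) + 1]] <- feat
    }
  }
  do.call(rbind, rows)
}

#' Before/after RF segmentation accuracy on a rejection corpus
#'
#' Trains the rejector on one corpus and measures mean LV-cavity (and
#' myocardium) 3D Dice on another, before and after slice rejection.
#'
#' @param corpus_train,corpus_test rejection corpora.
#' @param cfg an [rf_config].
#' @return list with the fitted `rejector` and a `summary` data.frame of mean
#'   Dice before/after per structure.
#' @export
rejection_experiment <- function(corpus_train, corpus_test,
                                 cfg = rf_config()) {
  rejector <- train_slice_rejector(rejection_features(corpus_train), cfg)
  labs <- c(lv_cavity = LABELS[["lv_cavity"]], lv_myo = LABELS[["lv_myo"]])
  before <- matrix(NA_real_, length(corpus_test), length(labs))
  after <- before
  for (i in seq_along(corpus_test)) {
    case <- corpus_test[[i]]
    corrected <- apply_slice_rejector(case$corrupted, rejector,
                                      case$softmax_list, case$images_list)
    for (j in seq_along(labs)) {
      before[i, j] <- dice3d(case$corrupted, case$truth$mask, labs[j])
      after[i, j] <- dice3d(corrected, case$truth$mask, labs[j])
    }
  }
  list(rejector = rejector,
       summary = data.frame(structure = names(labs),
                            dice_before = colMeans(before),
                            dice_after = colMeans(after)))
}

#' Train a slice rejector from a model's own predictions
#'
#' Runs the segmentation model (pre-rejection) on randomized phantoms and
#' labels each predicted slice by comparison with ground truth: a slice the
#' model segments that is empty in the ground truth is a discard example.
#' This is how the rejector is trained inside the full pipeline.
#'
#' @param model a trained `unet_model` of a static kind.
#' @param n_phantoms phantoms to segment for training data (enough that the
#'   forest sees the between-subject spread of the intensity feature).
#' @param seed integer seed.
#' @param cfg an [rf_config].
#' @return a `slice_rejector`.
#' @export
train_rejector_from_model <- function(model, n_phantoms = 30L, seed = 1L,
                                      cfg = rf_config()) {
  kind <- model$cfg$kind
  stopifnot(!kind %in% c("cine", "flow"))
  rows <- list()
  local_seed(seed, {
    for (i in seq_len(n_phantoms)) {
      ph <- make_phantom(sample_phantom_spec(kind, seed = sample.int(2^31 - 2, 1)))
      seg <- segment_stack(model, ph$image)
      ns <- n_slices(ph$image)
      for (s in seq_len(ns)) {
        feat <- extract_slice_features(seg$softmax[[s]], seg$images[[s]], s,
                                       ns, kind)
        if (is.null(feat)) next
        feat$discard <- sum(ph$truth$mask$labels[, , s]) == 0
        rows[[length(rows) + 1]] <- feat
      }
    }
  })
  train_slice_rejector(do.call(rbind, rows), cfg)
}
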