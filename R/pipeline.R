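# End-to-end segmentation: preprocess -> per-slice U-Net inference ->
# geometric post-processing -> optional RF slice rejection.

#' Post-process per-slice softmax maps into a clean mask
#'
#' Applies the fixed pipeline order: argmax, inverse resampling and stacking,
#' largest connected component per structure, per-slice convex hulls and —
#' for LGE and map kinds with a rejector supplied — RF slice rejection.
#'
#' @param softmax_list per-slice softmax arrays (slice-fastest, then frame).
#' @param records matching resample records from [preprocess_stack()].
#' @param kind sequence kind.
#' @param n_slices,n_frames stack geometry.
#' @param in_plane_spacing_mm,slice_thickness_mm,frame_duration_ms output
#'   calibration.
#' @param rejector optional trained `slice_rejector`.
#' @param images_list network-grid image slices (needed by the rejector's
#'   intensity feature).
#' @return a [cmr_mask].
#' @export
postprocess_softmax <- function(softmax_list, records, kind, n_slices,
                                n_frames = 1L, in_plane_spacing_mm,
                                slice_thickness_mm, frame_duration_ms = NULL,
                                rejector = NULL, images_list = NULL) {
  labels_list <- lapply(softmax_list, argmax_labels, kind = kind)
  mask <- stack_to_3d(labels_list, records, kind, n_slices, n_frames,
                      in_plane_spacing_mm, slice_thickness_mm,
                      frame_duration_ms)
  for (l in setdiff(kind_labels(kind), c(0L, LABELS[["scar"]])))
    mask <- largest_component(mask, l)
  mask <- convexify(mask)
  if (!kind %in% c("cine", "flow") && !is.null(rejector))
    mask <- apply_slice_rejector(mask, rejector, softmax_list, images_list)
  mask
}

#' Segment an image stack with a trained model
#'
#' @param model a trained `unet_model` whose kind matches the stack.
#' @param stack a [cmr_stack].
#' @param rejector optional `slice_rejector` for LGE/map kinds.
#' @param target_spacing_mm network-grid pixel spacing (the model's training
#'   convention; defaults to the stack's own spacing so phantom-resolution
#'   models see their native grid).
#' @return list with the final `mask` ([cmr_mask]), per-slice `softmax`,
#'   `records` and network-grid `images`.
#' @export
segment_stack <- function(model, stack, rejector = NULL,
                          target_spacing_mm = NULL) {
  stopifnot(inherits(model, "unet_model"), inherits(stack, "cmr_stack"))
  if (model$cfg$kind != stack$kind)
    stop(sprintf("model kind '%s' does not match stack kind '%s'",
                 model$cfg$kind, stack$kind))
  if (is.null(target_spacing_mm)) target_spacing_mm <- stack$in_plane_spacing_mm
  pp <- preprocess_stack(stack, target_shape = model$cfg$input_shape,
                         target_spacing_mm = target_spacing_mm)
  softmax_list <- lapply(pp$images, function(im) predict_slice(model, im))
  mask <- postprocess_softmax(softmax_list, pp$records, stack$kind,
                              pp$n_slices, pp$n_frames,
                              stack$in_plane_spacing_mm,
                              stack$slice_thickness_mm,
                              stack$frame_duration_ms,
                              rejector = rejector, images_list = pp$images)
  list(mask = mask, softmax = softmax_list, records = pp$records,
       images = pp$images)
}

#' Build a phantom training set of 2D slices
#'
#' Draws randomized phantoms (see [sample_phantom_spec()]) and collects
#' network-grid (image, mask) slice pairs until `n_slices_total` pairs are
#' available. Empty (background-only) slices are kept by default — rejecting
#' them is half the segmentation problem at the basal/apical extent — and at
#' most `max_per_phantom` slices are drawn per phantom so the budget is spent
#' on between-subject variation rather than near-duplicate frames.
#'
#' @param kind sequence kind.
#' @param n_slices_total number of 2D training pairs.
#' @param seed integer seed.
#' @param p_keep_empty retention probability for background-only slices.
#' @param max_per_phantom cap on slices drawn per phantom; temporal stacks
#'   contribute many near-duplicate slice/frame pairs, and capping them keeps
#'   the training set diverse in subjects rather than frames.
#' @param ... forwarded to [sample_phantom_spec()].
#' @return list with `images`, `masks` (lists of matrices) and the number of
#'   phantoms drawn.
#' @export
make_training_slices <- function(kind, n_slices_total = 200L, seed = 1L,
                                 p_keep_empty = 1.0, max_per_phantom = 8L,
                                 ...) {
  kind <- as_sequence_kind(kind)
  images <- list(); masks <- list()
  n_phantom <- 0
  local_seed(seed, {
    while (length(images) < n_slices_total) {
      n_phantom <- n_phantom + 1
      sp <- sample_phantom_spec(kind, seed = sample.int(2^31 - 2, 1), ...)
      ph <- make_phantom(sp)
      d <- dim(ph$image$voxels)
      nf <- if (length(d) == 4) d[4] else 1L
      stats <- list(mean = mean(ph$image$voxels),
                    sd = sd(as.vector(ph$image$voxels)))
      cand <- expand.grid(s = seq_len(d[3]), f = seq_len(nf))
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        msk <- if (length(d) == 4) ph$truth$mask$labels[, , cand$s[i], cand$f[i]]
               else ph$truth$mask$labels[, , cand$s[i]]
        keep[i] <- sum(msk) > 0 || runif(1) <= p_keep_empty
      }
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand) > max_per_phantom)
        cand <- cand[sample.int(nrow(cand), max_per_phantom), , drop = FALSE]
      for (i in seq_len(nrow(cand))) {
        if (length(images) >= n_slices_total) break
        s <- cand$s[i]; f <- cand$f[i]
        img <- if (length(d) == 4) ph$image$voxels[, , s, f] else ph$image$voxels[, , s]
        msk <- if (length(d) == 4) ph$truth$mask$labels[, , s, f] else ph$truth$mask$labels[, , s]
        ng <- to_network_grid(img, sp$in_plane_spacing_mm,
                              target_shape = dim(img),
                              target_spacing_mm = sp$in_plane_spacing_mm,
                              norm_stats = stats)
        images[[length(images) + 1]] <- ng$image
        masks[[length(masks) + 1]] <- msk
      }
    }
  })
  list(images = images, masks = masks, n_phantoms = n_phantom)
}
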