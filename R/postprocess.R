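# Post-processing: softmax maps become a clean 3D label mask. The order is
# fixed: per-pixel argmax -> inverse resampling and stacking on the original
# grid -> largest connected component per structure -> per-slice convex-hull
# regularization -> (LGE and maps only) random-forest slice rejection.

#' Per-pixel argmax labels from a softmax map
#'
#' Ties are broken toward the lowest class index.
#'
#' @param softmax array (H, W, K) of per-pixel class probabilities.
#' @param kind sequence kind mapping class indices to label codes.
#' @return integer label matrix.
#' @export
argmax_labels <- function(softmax, kind) {
  d <- dim(softmax)
  if (length(d) != 3) stop("softmax must be (H, W, K)")
  labs <- kind_labels(kind)
  if (d[3] != length(labs)) stop("class count does not match kind")
  m <- matrix(softmax, d[1] * d[2], d[3])
  cls <- max.col(m, ties.method = "first")
  matrix(labs[cls], d[1], d[2])
}

#' Stack per-slice label maps into a 3D (or 3D+t) mask
#'
#' Each network-grid label map is mapped back to its original slice grid via
#' its resample record, then slices (and frames) are stacked.
#'
#' @param labels_list list of network-grid label matrices, ordered slice-fastest
#'   then frame (as produced by [preprocess_stack()]).
#' @param records matching list of resample records.
#' @param kind sequence kind.
#' @param n_slices,n_frames stack geometry.
#' @param in_plane_spacing_mm,slice_thickness_mm,frame_duration_ms physical
#'   calibration of the output mask.
#' @return a [cmr_mask] on the original acquisition grid.
#' @export
stack_to_3d <- function(labels_list, records, kind, n_slices, n_frames = 1L,
                        in_plane_spacing_mm, slice_thickness_mm,
                        frame_duration_ms = NULL) {
  if (length(labels_list) != n_slices * n_frames)
    stop("need one label map per slice and frame")
  if (length(records) != length(labels_list))
    stop("need one resample record per label map")
  shp <- records[[1]]$original_shape
  for (r in records) if (!all(r$original_shape == shp))
    stop("inconsistent slice shapes across records")
  arr <- array(0L, c(shp[1], shp[2], n_slices, n_frames))
  i <- 0
  for (f in seq_len(n_frames)) for (s in seq_len(n_slices)) {
    i <- i + 1
    arr[, , s, f] <- from_network_grid(labels_list[[i]], records[[i]])
  }
  if (!kind_is_temporal(kind)) arr <- array(arr, c(shp[1], shp[2], n_slices))
  cmr_mask(arr, kind, in_plane_spacing_mm, slice_thickness_mm,
           frame_duration_ms)
}

lcc_volume <- function(vol, label, connectivity) {
  keep <- cpp_largest_component(vol, as.integer(label), as.integer(connectivity))
  vol[vol == label & !keep] <- 0L
  vol
}

#' Keep only the largest connected component of a structure
#'
#' 26-connectivity in 3D for cardiac structures; the aorta (label 5) is
#' handled per frame with 8-connectivity in-plane. Cine structures are
#' cleaned independently per frame. Equal-size ties keep the component whose
#' minimum (slice, row, col) index is lexicographically smallest.
#'
#' @param mask a [cmr_mask].
#' @param label label code to clean; no-op when the label is absent.
#' @return the cleaned [cmr_mask].
#' @export
largest_component <- function(mask, label) {
  stopifnot(inherits(mask, "cmr_mask"))
  conn <- if (label == LABELS[["aorta"]]) 8L else 26L
  d <- dim(mask$labels)
  if (length(d) == 4) {
    for (f in seq_len(d[4])) {
      vol <- array(mask$labels[, , , f], d[1:3])
      mask$labels[, , , f] <- lcc_volume(vol, label, conn)
    }
  } else {
    mask$labels <- lcc_volume(mask$labels, label, conn)
  }
  mask
}

# Logical fill of the convex hull of TRUE pixels (pixel centers inside the
# hull polygon, boundary inclusive). Fewer than 3 pixels: returned unchanged.
fill_hull_px <- function(bin) {
  pts <- which(bin, arr.ind = TRUE)
  if (nrow(pts) < 3) return(bin)
  h <- chull(pts[, 1], pts[, 2])
  poly <- pts[h, , drop = FALSE]
  if (nrow(poly) < 3) return(bin)
  out <- matrix(FALSE, nrow(bin), ncol(bin))
  rr <- range(poly[, 1]); cc <- range(poly[, 2])
  ri <- rr[1]:rr[2]; ci <- cc[1]:cc[2]
  px <- as.matrix(expand.grid(r = ri, c = ci))
  inside <- rep(TRUE, nrow(px))
  n <- nrow(poly)
  for (e in seq_len(n)) {
    a <- poly[e, ]; b <- poly[if (e == n) 1 else e + 1, ]
    cr <- (b[1] - a[1]) * (px[, 2] - a[2]) - (b[2] - a[2]) * (px[, 1] - a[1])
    inside <- inside & cr <= 1e-9
  }
  out[px[inside, , drop = FALSE]] <- TRUE
  out
}

convexify_slice <- function(lab) {
  old <- lab
  cav <- old == LABELS[["lv_cavity"]]
  myo <- old == LABELS[["lv_myo"]] | old == LABELS[["scar"]]
  if (any(cav) || any(myo)) {
    cav_h <- fill_hull_px(cav)
    epi_h <- fill_hull_px(cav | myo)
    lab[old == LABELS[["lv_cavity"]] | old == LABELS[["lv_myo"]]] <- 0L
    ring <- epi_h & !cav_h
    lab[ring] <- LABELS[["lv_myo"]]
    lab[cav_h] <- LABELS[["lv_cavity"]]
    # scar is exempt from convexification but clipped to the final myocardium
    lab[old == LABELS[["scar"]]] <- 0L
    lab[old == LABELS[["scar"]] & ring] <- LABELS[["scar"]]
    # the RV is not convexified; restore it where the hulls did not claim
    rv <- old == LABELS[["rv_cavity"]]
    lab[rv] <- 0L
    lab[rv & !epi_h & !cav_h] <- LABELS[["rv_cavity"]]
  }
  ao <- old == LABELS[["aorta"]]
  if (any(ao)) {
    ao_h <- fill_hull_px(ao)
    lab[ao] <- 0L
    lab[ao_h] <- LABELS[["aorta"]]
  }
  lab
}

#' Convex-hull regularization of a label mask
#'
#' Per 2D slice: the LV cavity becomes the convex hull of its pixels, the
#' epicardial region the hull of cavity plus myocardium, the myocardium the
#' epicardial hull minus the cavity hull (an annulus is not itself convex, so
#' convexity is enforced on the endo- and epicardial contours), and the aorta
#' the hull of its pixels. Scar keeps its shape but is clipped to the final
#' myocardial ring.
#'
#' @param mask a [cmr_mask] (normally after [largest_component()]).
#' @return the regularized [cmr_mask].
#' @export
convexify <- function(mask) {
  stopifnot(inherits(mask, "cmr_mask"))
  d <- dim(mask$labels)
  nf <- if (length(d) == 4) d[4] else 1L
  for (f in seq_len(nf)) for (s in seq_len(d[3])) {
    sl <- if (length(d) == 4) mask$labels[, , s, f] else mask$labels[, , s]
    sl <- convexify_slice(sl)
    if (length(d) == 4) mask$labels[, , s, f] <- sl else mask$labels[, , s] <- sl
  }
  mask
}

#' Random-forest slice-rejector configuration
#'
#' @param n_trees,max_depth forest size (defaults 6 and 6).
#' @param seed RNG seed.
#' @export
rf_config <- function(n_trees = 6L, max_depth = 6L, seed = 1L) {
  stopifnot(n_trees >= 1, max_depth >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth), seed = as.integer(seed)),
            class = "rf_config")
}

#' Per-slice features for the over-segmentation rejector
#'
#' The three features are the mean softmax of the predicted myocardium, the
#' mean (normalized) image intensity over those pixels, and the normalized
#' slice position `(slice_index - 1) / (n_slices - 1)`.
#'
#' @param softmax array (H, W, K) for the slice.
#' @param image_slice matching network-grid (z-scored) image.
#' @param slice_index 1-based slice index (1 = most basal).
#' @param n_slices total slices in the stack.
#' @param kind sequence kind.
#' @return one-row data.frame, or `NULL` when the slice contains no predicted
#'   myocardium (such slices are auto-discarded without consulting the RF).
#' @export
extract_slice_features <- function(softmax, image_slice, slice_index,
                                   n_slices, kind) {
  labs <- kind_labels(kind)
  myo_cls <- match(LABELS[["lv_myo"]], labs)
  if (is.na(myo_cls)) stop(sprintf("kind '%s' has no myocardium class", kind))
  pred <- argmax_labels(softmax, kind)
  sel <- pred == LABELS[["lv_myo"]]
  if (!any(sel)) return(NULL)
  data.frame(
    mean_softmax_myo = mean(softmax[, , myo_cls][sel]),
    mean_intensity_myo = mean(image_slice[sel]),
    norm_slice_pos = if (n_slices > 1) (slice_index - 1) / (n_slices - 1) else 0)
}

#' Train the over-segmentation slice rejector
#'
#' A random forest classifying slices as keep/discard from
#' [extract_slice_features()] rows; discard labels come from comparing model
#' output against ground truth (a slice segmented by the model but empty in
#' the ground truth is a discard example).
#'
#' @param features data.frame with the three feature columns and a logical
#'   `discard` column.
#' @param cfg an [rf_config].
#' @return a `slice_rejector` with the fitted forest and its training
#'   accuracy.
#' @export
train_slice_rejector <- function(features, cfg = rf_config()) {
  stopifnot(is.data.frame(features), "discard" %in% names(features))
  if (length(unique(features$discard)) < 2)
    stop("training data must contain both keep and discard slices")
  df <- features
  df$discard <- factor(df$discard, levels = c(FALSE, TRUE))
  # probability forest with a strict 0.5 threshold: with an even tree count,
  # hard-vote prediction breaks 50/50 ties at random, which would make the
  # pipeline non-reproducible and occasionally discard true slices; a tied
  # vote keeps the slice. With only three features, per-split subsampling
  # (the mtry = 1 default) lets one weak feature dominate trees, so every
  # split considers all three.
  fit <- ranger::ranger(
    discard ~ mean_softmax_myo + mean_intensity_myo + norm_slice_pos,
    data = df, num.trees = cfg$n_trees, max.depth = cfg$max_depth,
    mtry = 3, probability = TRUE, seed = cfg$seed)
  pred <- predict(fit, df)$predictions[, "TRUE"] > 0.5
  acc <- mean(pred == (df$discard == "TRUE"))
  structure(list(forest = fit, cfg = cfg, train_accuracy = acc),
            class = "slice_rejector")
}

#' Predict discard decisions for slice features
#' @param rejector a `slice_rejector`.
#' @param features data.frame of feature rows.
#' @return logical vector (TRUE = discard): the fraction of trees voting
#'   discard must strictly exceed 0.5, so tied votes keep the slice.
#' @export
predict_rejector <- function(rejector, features) {
  stopifnot(inherits(rejector, "slice_rejector"))
  predict(rejector$forest, features)$predictions[, "TRUE"] > 0.5
}

#' Remove over-segmented slices from a static-kind mask
#'
#' Applies the rejector per slice: rejected slices are set entirely to
#' background, all others untouched. Only LGE and map kinds are eligible;
#' cine and flow masks are refused. Slices with no predicted myocardium are
#' discarded without consulting the forest.
#'
#' @param mask a 3D [cmr_mask] (LGE or map kind).
#' @param rejector a trained `slice_rejector`, or `NULL` for the identity.
#' @param softmax_list per-slice softmax arrays.
#' @param images_list per-slice network-grid images.
#' @return the corrected [cmr_mask].
#' @export
apply_slice_rejector <- function(mask, rejector, softmax_list, images_list) {
  stopifnot(inherits(mask, "cmr_mask"))
  if (mask$kind %in% c("cine", "flow"))
    stop(sprintf("slice rejection does not apply to kind '%s'", mask$kind))
  if (is.null(rejector)) return(mask)
  ns <- n_slices(mask)
  for (s in seq_len(ns)) {
    if (sum(mask$labels[, , s]) == 0) next
    feat <- extract_slice_features(softmax_list[[s]], images_list[[s]], s, ns,
                                   mask$kind)
    drop_slice <- if (is.null(feat)) TRUE else predict_rejector(rejector, feat)
    if (drop_slice) mask$labels[, , s] <- 0L
  }
  mask
}
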