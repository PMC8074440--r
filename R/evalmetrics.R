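# Segmentation agreement metrics (3D Dice, Hausdorff, mean surface distance)
# and parameter agreement statistics (Pearson R, mean errors, Bland-Altman).
# Surfaces are voxels of the structure with at least one face-adjacent
# non-structure neighbor (array borders count); distances are measured
# between voxel centers in physical mm coordinates.

as_label_array <- function(x) {
  if (inherits(x, "cmr_mask")) x$labels else as.array(x)
}

check_same_grid <- function(a, b) {
  da <- dim(as_label_array(a)); db <- dim(as_label_array(b))
  if (length(da) != length(db) || !all(da == db))
    stop("masks are not on the same grid")
}

#' 3D Dice coefficient for one structure
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks are defined as perfectly
#' agreeing (Dice 1); one empty mask gives 0.
#'
#' @param a,b label masks ([cmr_mask] or integer arrays) on the same grid.
#' @param label label code of the structure.
#' @return Dice in \[0, 1\].
#' @export
dice3d <- function(a, b, label) {
  check_same_grid(a, b)
  av <- as_label_array(a) == label
  bv <- as_label_array(b) == label
  na <- sum(av); nb <- sum(bv)
  if (na + nb == 0) return(1)
  2 * sum(av & bv) / (na + nb)
}

# Face-adjacency boundary of a binary 3D volume.
boundary_mask <- function(bin) {
  d <- dim(bin)
  interior <- array(TRUE, d)
  shift_ok <- function(axis, by) {
    out <- array(FALSE, d)
    n <- d[axis]
    if (n == 1) return(out)  # a 1-voxel-thick axis is all boundary
    idx <- lapply(d, seq_len)
    src <- idx; dst <- idx
    if (by == 1) { dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1) }
    else { dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- bin[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (axis in 1:3) for (by in c(-1, 1))
    interior <- interior & shift_ok(axis, by)
  bin & !interior
}

boundary_points_mm <- function(vol, label, spacing) {
  bin <- vol == label
  if (!any(bin)) return(NULL)
  bd <- boundary_mask(bin)
  idx <- which(bd, arr.ind = TRUE)
  cbind(idx[, 1] * spacing[1], idx[, 2] * spacing[2], idx[, 3] * spacing[3])
}

surface_dists <- function(a, b, label, spacing) {
  av <- as_label_array(a); bv <- as_label_array(b)
  d <- dim(av)
  frames <- if (length(d) == 4) seq_len(d[4]) else 1L
  hds <- c(); msds <- c()
  for (f in frames) {
    va <- if (length(d) == 4) av[, , , f, drop = TRUE] else av
    vb <- if (length(d) == 4) bv[, , , f, drop = TRUE] else bv
    if (length(dim(va)) < 3) dim(va) <- c(dim(va), 1L)
    if (length(dim(vb)) < 3) dim(vb) <- c(dim(vb), 1L)
    pa <- boundary_points_mm(va, label, spacing)
    pb <- boundary_points_mm(vb, label, spacing)
    if (is.null(pa) && is.null(pb)) next
    if (is.null(pa) || is.null(pb)) return(list(hd = NA_real_, msd = NA_real_))
    dab <- cpp_min_dists(pa, pb)
    dba <- cpp_min_dists(pb, pa)
    hds <- c(hds, max(max(dab), max(dba)))
    msds <- c(msds, (mean(dab) + mean(dba)) / 2)
  }
  if (length(hds) == 0) return(list(hd = NA_real_, msd = NA_real_))
  list(hd = max(hds), msd = mean(msds))
}

get_spacing <- function(a, spacing) {
  if (!is.null(spacing)) return(rep_len(spacing, 3))
  if (inherits(a, "cmr_mask"))
    return(c(a$in_plane_spacing_mm, a$slice_thickness_mm))
  stop("spacing required for plain arrays")
}

#' 3D Hausdorff distance for one structure (mm)
#'
#' Maximum over the two directed Hausdorff distances between the boundary
#' voxel point sets, with anisotropic physical spacing applied. Temporal
#' masks report the maximum over frames. Returns `NA` when either side is
#' empty (the metric is undefined there).
#'
#' @inheritParams dice3d
#' @param spacing physical spacing `c(row, col, slice)` in mm; taken from the
#'   mask when omitted.
#' @export
hausdorff3d <- function(a, b, label, spacing = NULL) {
  check_same_grid(a, b)
  surface_dists(a, b, label, get_spacing(a, spacing))$hd
}

#' 3D mean surface distance for one structure (mm)
#'
#' Symmetric mean: the average of the mean boundary-to-boundary nearest
#' distances in the two directions. Temporal masks report the mean over
#' frames. `NA` when either side is empty.
#'
#' @inheritParams hausdorff3d
#' @export
mean_surface_distance <- function(a, b, label, spacing = NULL) {
  check_same_grid(a, b)
  surface_dists(a, b, label, get_spacing(a, spacing))$msd
}

#' Evaluate a predicted mask against ground truth
#'
#' @param pred,truth [cmr_mask]s on the same grid.
#' @param labels label codes to evaluate (default: all non-background labels
#'   legal for the kind).
#' @return data.frame with one row per structure: dice, hd_mm, msd_mm and
#'   voxel counts.
#' @export
evaluate_masks <- function(pred, truth, labels = NULL) {
  stopifnot(inherits(pred, "cmr_mask"), inherits(truth, "cmr_mask"))
  if (is.null(labels)) labels <- setdiff(kind_labels(truth$kind), 0L)
  rows <- lapply(labels, function(l) {
    sd_ <- surface_dists(pred, truth, l,
                         c(pred$in_plane_spacing_mm, pred$slice_thickness_mm))
    data.frame(label = l, structure = names(LABELS)[match(l, LABELS)],
               dice = dice3d(pred, truth, l), hd_mm = sd_$hd, msd_mm = sd_$msd,
               n_pred = sum(as_label_array(pred) == l),
               n_truth = sum(as_label_array(truth) == l))
  })
  do.call(rbind, rows)
}

#' Agreement statistics between automatic and reference parameters
#'
#' Pearson correlation, the mean error (absolute difference for
#' percentage-based parameters such as EF and scar percentage; absolute
#' relative difference, in percent, for numerical parameters), and
#' Bland-Altman bias with 1.96-SD limits of agreement.
#'
#' @param auto,ref paired numeric vectors (length >= 3 for a correlation).
#' @param param_kind `"percentage"` or `"numerical"`.
#' @return data.frame with `pearson_r`, `mean_error`, `bias`, `loa_low`,
#'   `loa_high` and `n`.
#' @export
agreement <- function(auto, ref, param_kind = c("percentage", "numerical")) {
  param_kind <- match.arg(param_kind)
  ok <- is.finite(auto) & is.finite(ref)
  auto <- auto[ok]; ref <- ref[ok]
  n <- length(auto)
  if (n < 3) stop("need at least 3 paired values")
  r <- if (sd(auto) < 1e-12 || sd(ref) < 1e-12) NA_real_ else cor(auto, ref)
  me <- if (param_kind == "percentage") mean(abs(auto - ref))
        else 100 * mean(abs(auto - ref) / abs(ref))
  diffs <- auto - ref
  bias <- mean(diffs); s <- sd(diffs)
  data.frame(pearson_r = r, mean_error = me, bias = bias,
             loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s, n = n)
}
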