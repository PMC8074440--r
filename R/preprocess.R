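# Pre-processing: every 2D slice is brought to a fixed network grid
# (default 212 x 212 pixels at 1.37 x 1.37 mm) with z-scored intensity
# (stack-level statistics when a whole stack is processed); the transform is
# recorded so label maps can be mapped back.

#' Resample a 2D slice to the network grid
#'
#' The physical field of view is resampled to the target pixel spacing
#' (bilinear), z-scored, then center-cropped / zero-padded to the target
#' shape. The returned record suffices to invert the spatial transform for
#' label maps with [from_network_grid()].
#'
#' @param slice2d numeric matrix.
#' @param spacing_mm input pixel spacing, scalar or length-2 (row, col).
#' @param target_shape output grid, default `c(212, 212)`.
#' @param target_spacing_mm output spacing, default `c(1.37, 1.37)`.
#' @param normalize z-score the intensities (with a zero-variance guard that
#'   maps constant slices to all zeros). Disable to resample physical values
#'   (e.g. relaxation maps for parameter extraction).
#' @param norm_stats optional `list(mean, sd)` used instead of the slice's own
#'   statistics — [preprocess_stack()] passes stack-level statistics so that
#'   empty slices stay flat instead of having their noise amplified to unit
#'   variance.
#' @return list with `image` (matrix of `target_shape`) and `record` (a
#'   `resample_record`).
#' @export
to_network_grid <- function(slice2d, spacing_mm,
                            target_shape = c(212L, 212L),
                            target_spacing_mm = c(1.37, 1.37),
                            normalize = TRUE, norm_stats = NULL) {
  if (length(slice2d) == 0 || is.null(dim(slice2d)))
    stop("empty image")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 2L)
  target_spacing_mm <- rep_len(as.numeric(target_spacing_mm), 2L)
  if (any(spacing_mm <= 0)) stop("non-positive spacing")
  osz <- dim(slice2d)
  rsz <- pmax(1L, as.integer(round(osz * spacing_mm / target_spacing_mm)))
  res <- if (all(rsz == osz)) slice2d else
    EBImage::resize(slice2d, w = rsz[1], h = rsz[2], filter = "bilinear")
  shift <- 0; scale <- 1
  if (normalize) {
    if (is.null(norm_stats)) {
      mu <- mean(res); s <- sd(as.vector(res))
    } else { mu <- norm_stats$mean; s <- norm_stats$sd }
    if (!is.finite(s) || s < 1e-6) { res[] <- 0; shift <- mu; scale <- 1
    } else { res <- (res - mu) / s; shift <- mu; scale <- s }
  }
  out <- matrix(0, target_shape[1], target_shape[2])
  len <- pmin(rsz, target_shape)
  src0 <- pmax(0L, as.integer(floor((rsz - target_shape) / 2)))
  dst0 <- pmax(0L, as.integer(floor((target_shape - rsz) / 2)))
  out[dst0[1] + seq_len(len[1]), dst0[2] + seq_len(len[2])] <-
    res[src0[1] + seq_len(len[1]), src0[2] + seq_len(len[2])]
  record <- structure(list(original_shape = osz,
                           original_spacing_mm = spacing_mm,
                           resampled_shape = rsz,
                           target_shape = as.integer(target_shape),
                           target_spacing_mm = target_spacing_mm,
                           intensity_shift = shift, intensity_scale = scale),
                      class = "resample_record")
  list(image = out, record = record)
}

#' Map a network-grid label map back to the original slice grid
#'
#' Inverts the crop/pad, then resamples nearest-neighbor back to the original
#' shape, so output labels are drawn only from the input's label set.
#'
#' @param mask2d integer matrix on the network grid.
#' @param record the `resample_record` from [to_network_grid()].
#' @return integer matrix on the original grid.
#' @export
from_network_grid <- function(mask2d, record) {
  stopifnot(inherits(record, "resample_record"))
  if (!all(dim(mask2d) == record$target_shape))
    stop("mask shape does not match the resample record")
  rsz <- record$resampled_shape
  mid <- matrix(0L, rsz[1], rsz[2])
  len <- pmin(rsz, record$target_shape)
  src0 <- pmax(0L, as.integer(floor((rsz - record$target_shape) / 2)))
  dst0 <- pmax(0L, as.integer(floor((record$target_shape - rsz) / 2)))
  mid[src0[1] + seq_len(len[1]), src0[2] + seq_len(len[2])] <-
    mask2d[dst0[1] + seq_len(len[1]), dst0[2] + seq_len(len[2])]
  out <- if (all(rsz == record$original_shape)) mid else
    EBImage::resize(mid, w = record$original_shape[1],
                    h = record$original_shape[2], filter = "none")
  storage.mode(out) <- "integer"
  out
}

# Preprocess every slice (and frame) of a stack; returns network-grid slice
# images plus one record per (slice, frame). Normalization uses stack-level
# statistics: a per-slice z-score would blow empty slices' noise up to unit
# variance, which reads as tissue to a 2D network.
preprocess_stack <- function(stack, target_shape = c(212L, 212L),
                             target_spacing_mm = c(1.37, 1.37)) {
  stopifnot(inherits(stack, "cmr_stack"))
  d <- dim(stack$voxels)
  nf <- if (length(d) == 4) d[4] else 1L
  ns <- d[3]
  stats <- list(mean = mean(stack$voxels), sd = sd(as.vector(stack$voxels)))
  images <- vector("list", ns * nf)
  records <- vector("list", ns * nf)
  i <- 0
  for (f in seq_len(nf)) for (s in seq_len(ns)) {
    sl <- if (length(d) == 4) stack$voxels[, , s, f] else stack$voxels[, , s]
    r <- to_network_grid(sl, stack$in_plane_spacing_mm, target_shape,
                         target_spacing_mm, norm_stats = stats)
    i <- i + 1
    images[[i]] <- r$image; records[[i]] <- r$record
  }
  list(images = images, records = records, n_slices = ns, n_frames = nf)
}
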