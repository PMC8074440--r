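#' Spatially calibrated CMR image stack
#'
#' A `cmr_stack` wraps a numeric voxel array with its physical calibration and
#' sequence kind. Static kinds (LGE, T1/T2 maps) are 3D arrays indexed
#' `[row, col, slice]`; temporal kinds (cine, flow) are 4D arrays indexed
#' `[row, col, slice, frame]`. Slice index 1 is the most basal slice; the
#' normalized slice position of slice `i` is `(i - 1) / (n_slices - 1)`.
#'
#' @param voxels numeric array, 3D or 4D as above.
#' @param kind a sequence kind, see [SEQUENCE_KINDS].
#' @param in_plane_spacing_mm positive length-2 numeric (row, col spacing).
#' @param slice_thickness_mm positive scalar.
#' @param frame_duration_ms positive scalar; required only for temporal kinds
#'   (defaults to an 800 ms cardiac cycle divided by the frame count).
#' @return an object of class `cmr_stack`.
#' @export
cmr_stack <- function(voxels, kind, in_plane_spacing_mm,
                      slice_thickness_mm, frame_duration_ms = NULL) {
  kind <- as_sequence_kind(kind)
  voxels <- as.array(voxels)
  nd <- length(dim(voxels))
  if (kind_is_temporal(kind) && nd != 4)
    stop(sprintf("kind '%s' requires a 4D [row, col, slice, frame] array", kind))
  if (!kind_is_temporal(kind) && nd != 3)
    stop(sprintf("kind '%s' requires a 3D [row, col, slice] array", kind))
  in_plane_spacing_mm <- rep_len(as.numeric(in_plane_spacing_mm), 2L)
  if (any(!is.finite(in_plane_spacing_mm)) || any(in_plane_spacing_mm <= 0) ||
      !is.finite(slice_thickness_mm) || slice_thickness_mm <= 0)
    stop("non-positive spacing")
  if (kind_is_temporal(kind)) {
    if (is.null(frame_duration_ms))
      frame_duration_ms <- 800 / dim(voxels)[4]
    if (frame_duration_ms <= 0) stop("non-positive frame duration")
  } else {
    frame_duration_ms <- NULL
  }
  structure(
    list(voxels = voxels, kind = kind,
         in_plane_spacing_mm = in_plane_spacing_mm,
         slice_thickness_mm = as.numeric(slice_thickness_mm),
         frame_duration_ms = frame_duration_ms,
         intensity_units = kind_units(kind)),
    class = "cmr_stack")
}

#' @export
print.cmr_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<cmr_stack> kind=%s dims=[%s] spacing=%.3gx%.3g mm, slice %.3g mm%s\n",
              x$kind, paste(d, collapse = "x"),
              x$in_plane_spacing_mm[1], x$in_plane_spacing_mm[2],
              x$slice_thickness_mm,
              if (!is.null(x$frame_duration_ms))
                sprintf(", frame %.3g ms", x$frame_duration_ms) else ""))
  invisible(x)
}

#' Anatomical label mask aligned to a [cmr_stack]
#'
#' @param labels integer array on the same grid as its image stack (3D, or 4D
#'   for temporal kinds). Labels must come from [LABELS] and be legal for
#'   `kind` (see [kind_labels]).
#' @inheritParams cmr_stack
#' @return an object of class `cmr_mask`.
#' @export
cmr_mask <- function(labels, kind, in_plane_spacing_mm, slice_thickness_mm,
                     frame_duration_ms = NULL) {
  kind <- as_sequence_kind(kind)
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  check_labels_legal(labels, kind)
  obj <- cmr_stack(array(0, dim = dim(labels)), kind, in_plane_spacing_mm,
                   slice_thickness_mm, frame_duration_ms)
  obj$voxels <- NULL
  obj$labels <- labels
  obj$intensity_units <- NULL
  class(obj) <- "cmr_mask"
  obj
}

#' @export
print.cmr_mask <- function(x, ...) {
  cat(sprintf("<cmr_mask> kind=%s dims=[%s] labels={%s}\n", x$kind,
              paste(dim(x$labels), collapse = "x"),
              paste(sort(unique(as.integer(x$labels))), collapse = ",")))
  invisible(x)
}

#' Number of slices / frames in a stack or mask
#' @param x a `cmr_stack` or `cmr_mask`.
#' @export
n_slices <- function(x) dim(if (inherits(x, "cmr_mask")) x$labels else x$voxels)[3]

#' @rdname n_slices
#' @export
n_frames <- function(x) {
  d <- dim(if (inherits(x, "cmr_mask")) x$labels else x$voxels)
  if (length(d) == 4) d[4] else 1L
}

#' Voxel volume in cubic millimetres
#' @param x a `cmr_stack` or `cmr_mask`.
#' @export
voxel_volume_mm3 <- function(x) {
  prod(x$in_plane_spacing_mm) * x$slice_thickness_mm
}

sidecar_path <- function(path) paste0(path, ".yaml")

#' Write an image stack to a NIfTI-1 file
#'
#' Spacing is stored in the NIfTI header; for temporal kinds the frame
#' duration is additionally written to a small `<path>.yaml` sidecar (NIfTI
#' time units are not reliably preserved by all tools).
#'
#' @param stack a [cmr_stack].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "cmr_stack"))
  pd <- c(stack$in_plane_spacing_mm, stack$slice_thickness_mm)
  if (!is.null(stack$frame_duration_ms)) pd <- c(pd, stack$frame_duration_ms / 1000)
  img <- RNifti::asNifti(stack$voxels)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  if (!is.null(stack$frame_duration_ms)) {
    yaml::write_yaml(list(kind = stack$kind,
                          frame_duration_ms = stack$frame_duration_ms),
                     sidecar_path(path))
  }
  invisible(path)
}

#' Read an image stack from a NIfTI-1 file
#'
#' @param path NIfTI file path.
#' @param kind sequence kind of the stored stack (NIfTI carries no sequence
#'   information; the study manifest supplies it).
#' @param frame_duration_ms optional override; otherwise taken from the YAML
#'   sidecar, then the header, then the 800 ms cycle default.
#' @return a [cmr_stack].
#' @export
read_stack <- function(path, kind, frame_duration_ms = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  kind <- as_sequence_kind(kind)
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stop("non-positive spacing in NIfTI header")
  vox <- as.array(img)
  attributes(vox) <- list(dim = dim(vox))  # drop niftiImage bookkeeping
  nd <- length(dim(vox))
  if (kind_is_temporal(kind) && nd == 3)
    stop(sprintf("kind '%s' needs a temporal axis but '%s' is 3D", kind, path))
  if (!kind_is_temporal(kind) && nd == 4) {
    if (dim(vox)[4] != 1)
      stop(sprintf("kind '%s' is static but '%s' has %d frames", kind, path,
                   dim(vox)[4]))
    vox <- array(vox, dim = dim(vox)[1:3])
  }
  if (kind_is_temporal(kind) && is.null(frame_duration_ms)) {
    sc <- sidecar_path(path)
    if (file.exists(sc)) {
      frame_duration_ms <- yaml::read_yaml(sc)$frame_duration_ms
    } else if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0) {
      frame_duration_ms <- pd[4] * 1000
    }
  }
  cmr_stack(vox, kind, pd[1:2], pd[3], frame_duration_ms)
}

#' Write a label mask to an integer NIfTI-1 file
#'
#' @param mask a [cmr_mask]; labels must be legal for its kind.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "cmr_mask"))
  check_labels_legal(mask$labels, mask$kind)
  pd <- c(mask$in_plane_spacing_mm, mask$slice_thickness_mm)
  if (!is.null(mask$frame_duration_ms)) pd <- c(pd, mask$frame_duration_ms / 1000)
  img <- RNifti::asNifti(mask$labels)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = "int16")
  if (!is.null(mask$frame_duration_ms)) {
    yaml::write_yaml(list(kind = mask$kind,
                          frame_duration_ms = mask$frame_duration_ms),
                     sidecar_path(path))
  }
  invisible(path)
}

#' Read a label mask from a NIfTI-1 file
#' @inheritParams read_stack
#' @return a [cmr_mask].
#' @export
read_mask <- function(path, kind, frame_duration_ms = NULL) {
  s <- read_stack(path, kind, frame_duration_ms)
  m <- round(s$voxels)
  cmr_mask(m, kind, s$in_plane_spacing_mm, s$slice_thickness_mm,
           s$frame_duration_ms)
}

#' Read a study manifest
#'
#' A manifest is a CSV with columns `subject_id`, `kind`, `image_path` and
#' optionally `mask_path`; one row per subject/sequence pair. Relative paths
#' are resolved against the manifest's directory.
#'
#' @param path CSV file path.
#' @return a data.frame with validated kinds and absolute paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "kind", "image_path")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols) > 0)
    stop(sprintf("manifest lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  m$kind <- vapply(m$kind, as_sequence_kind, character(1))
  if (anyDuplicated(m[c("subject_id", "kind")]))
    stop("manifest has duplicate subject/kind pairs")
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(is.na(p) | p == "", NA_character_,
                            ifelse(grepl("^/", p), p, file.path(base, p)))
  m$image_path <- fix(m$image_path)
  if (is.null(m$mask_path)) m$mask_path <- NA_character_ else m$mask_path <- fix(m$mask_path)
  m
}
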