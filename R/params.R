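# Clinical parameter extraction from a final label mask: cavity volumes and
# ejection fractions from cine, LV mass (1.05 g/mL at end-diastole), scar
# percentage from LGE, mean myocardial relaxation times from the maps, and
# net/backward aortic flow from phase-contrast velocity images.

#' Volume of a labeled structure (mL)
#'
#' Voxel summation: `count * voxel_volume_mm3 / 1000`.
#'
#' @param mask a [cmr_mask].
#' @param label label code.
#' @param frame frame index for temporal masks (default 1).
#' @return volume in mL.
#' @export
structure_volume <- function(mask, label, frame = 1L) {
  stopifnot(inherits(mask, "cmr_mask"))
  d <- dim(mask$labels)
  vol <- if (length(d) == 4) mask$labels[, , , frame, drop = TRUE] else mask$labels
  sum(vol == label) * voxel_volume_mm3(mask) / 1000
}

lv_volume_curve <- function(mask, label = LABELS[["lv_cavity"]]) {
  vapply(seq_len(n_frames(mask)), function(f) structure_volume(mask, label, f),
         numeric(1))
}

#' Identify the end-diastolic and end-systolic frames of a cine mask
#'
#' ED is the frame with maximal LV-cavity volume, ES the frame with minimal
#' volume; ties resolve to the earliest frame.
#'
#' @param mask a 4D cine [cmr_mask] with at least 2 frames containing LV
#'   cavity.
#' @return list with `ed_frame` and `es_frame` (1-based).
#' @export
find_ed_es <- function(mask) {
  stopifnot(inherits(mask, "cmr_mask"), mask$kind == "cine")
  v <- lv_volume_curve(mask)
  if (sum(v > 0) < 2) stop("need at least 2 frames with a nonzero LV cavity")
  list(ed_frame = which.max(v), es_frame = which.min(v))
}

#' Ejection fraction (%)
#'
#' `100 * (EDV - ESV) / EDV`. An ESV exceeding the EDV (possible under
#' segmentation error) is clamped to EF = 0 with a warning.
#'
#' @param edv,esv end-diastolic / end-systolic volume (mL), `edv > 0`.
#' @export
ejection_fraction <- function(edv, esv) {
  if (edv <= 0) stop("EDV must be positive")
  if (esv > edv) {
    warning("ESV exceeds EDV; EF clamped to 0")
    return(0)
  }
  100 * (edv - esv) / edv
}

#' Left-ventricular mass (g)
#'
#' Myocardial volume at end-diastole times the 1.05 g/mL muscle density
#' convention.
#'
#' @param mask a [cmr_mask] containing myocardium.
#' @param frame frame to measure at (the ED frame for cine).
#' @export
lv_mass <- function(mask, frame = 1L) {
  structure_volume(mask, LABELS[["lv_myo"]], frame) * 1.05
}

#' Scar percentage within the myocardium
#'
#' `100 * scar / (myocardium + scar)`: scar counts as diseased myocardium,
#' so the denominator is the whole muscle.
#'
#' @param mask an LGE [cmr_mask].
#' @export
scar_percentage <- function(mask) {
  v_scar <- structure_volume(mask, LABELS[["scar"]])
  v_myo <- structure_volume(mask, LABELS[["lv_myo"]])
  if (v_myo + v_scar <= 0) stop("empty myocardium")
  100 * v_scar / (v_myo + v_scar)
}

#' Otsu threshold of a sample of intensities
#'
#' Maximizes the between-class variance over a 256-bin histogram; returns the
#' threshold on the original intensity scale (shift-invariant).
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param n_bins histogram resolution.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  rng <- range(values)
  if (diff(rng) <= 0) stop("constant intensities: threshold undefined")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(pmin(findInterval(values, edges, rightmost.closed = TRUE),
                     n_bins), nbins = n_bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  edges[which.max(bcv) + 1]
}

#' Semi-automatic scar extraction by Otsu thresholding
#'
#' Computes the Otsu threshold on the within-myocardium intensities of an LGE
#' image and labels the hyperenhanced (brighter) pixels as scar.
#'
#' @param image an LGE [cmr_stack].
#' @param mask a [cmr_mask] whose myocardium region (myocardium or scar
#'   labels) defines the sampling region.
#' @return logical array marking scar voxels within the myocardium region.
#' @export
otsu_scar_from_intensity <- function(image, mask) {
  stopifnot(inherits(image, "cmr_stack"), inherits(mask, "cmr_mask"))
  region <- mask$labels == LABELS[["lv_myo"]] | mask$labels == LABELS[["scar"]]
  vals <- image$voxels[region]
  thr <- otsu_threshold(vals)
  region & image$voxels > thr
}

#' Mean relaxation time within the myocardium (ms)
#'
#' Arithmetic mean of the raw map values over myocardium voxels across all
#' slices.
#'
#' @param image a T1/T2 map [cmr_stack] (values in ms).
#' @param mask matching [cmr_mask].
#' @export
map_mean <- function(image, mask) {
  sel <- mask$labels == LABELS[["lv_myo"]]
  if (!any(sel)) stop("empty myocardium")
  mean(image$voxels[sel])
}

#' Net and backward aortic flow (mL)
#'
#' Per frame `Q_f = sum_{pixels in aorta} v * a` (v in cm/s, pixel area a);
#' net flow is `sum_f Q_f * dt` and backward flow `|sum_f min(Q_f, 0) * dt|`,
#' converted to mL. Positive velocity is antegrade.
#'
#' @param image a flow [cmr_stack] (velocities in cm/s) with frame duration.
#' @param mask matching temporal [cmr_mask] with aorta labels.
#' @return list with `net_flow_ml`, `backward_flow_ml` and the per-frame flow
#'   rates `frame_flow_mm3_s`.
#' @export
flow_amplitudes <- function(image, mask) {
  stopifnot(inherits(image, "cmr_stack"), image$kind == "flow")
  if (is.null(image$frame_duration_ms)) stop("missing frame duration")
  nf <- n_frames(image)
  a_mm2 <- prod(image$in_plane_spacing_mm)
  q <- vapply(seq_len(nf), function(f) {
    sel <- mask$labels[, , , f] == LABELS[["aorta"]]
    sum(image$voxels[, , , f][sel]) * 10 * a_mm2  # cm/s -> mm/s
  }, numeric(1))
  dt_s <- image$frame_duration_ms / 1000
  list(net_flow_ml = sum(q) * dt_s / 1000,
       backward_flow_ml = abs(sum(pmin(q, 0)) * dt_s / 1000),
       frame_flow_mm3_s = q)
}

#' Extract the clinical parameters for a mask's sequence kind
#'
#' Dispatches on the mask kind: cine yields ED/ES frames, LV/RV volumes, SV,
#' EF and LV mass; LGE yields the scar percentage; maps the mean myocardial
#' relaxation time; flow the net and backward flow amplitudes.
#'
#' @param image the underlying [cmr_stack] (needed for map and flow
#'   parameters; optional for cine/LGE).
#' @param mask the final [cmr_mask].
#' @return a named list of class `cardiac_params`.
#' @export
extract_params <- function(mask, image = NULL) {
  stopifnot(inherits(mask, "cmr_mask"))
  kind <- mask$kind
  out <- list(kind = kind)
  if (kind == "cine") {
    fr <- find_ed_es(mask)
    out$ed_frame <- fr$ed_frame; out$es_frame <- fr$es_frame
    out$lv_edv_ml <- structure_volume(mask, LABELS[["lv_cavity"]], fr$ed_frame)
    out$lv_esv_ml <- structure_volume(mask, LABELS[["lv_cavity"]], fr$es_frame)
    out$lv_sv_ml <- out$lv_edv_ml - out$lv_esv_ml
    out$lv_ef_pct <- ejection_fraction(out$lv_edv_ml, out$lv_esv_ml)
    out$lv_mass_g <- lv_mass(mask, fr$ed_frame)
    rv_ed <- structure_volume(mask, LABELS[["rv_cavity"]], fr$ed_frame)
    if (rv_ed > 0) {
      out$rv_edv_ml <- rv_ed
      out$rv_esv_ml <- structure_volume(mask, LABELS[["rv_cavity"]], fr$es_frame)
      out$rv_sv_ml <- out$rv_edv_ml - out$rv_esv_ml
      out$rv_ef_pct <- ejection_fraction(out$rv_edv_ml, out$rv_esv_ml)
    }
  } else if (kind == "lge") {
    out$scar_pct <- scar_percentage(mask)
    out$lv_myo_ml <- structure_volume(mask, LABELS[["lv_myo"]]) +
      structure_volume(mask, LABELS[["scar"]])
  } else if (kind %in% c("t1_native", "t1_post", "t2")) {
    if (is.null(image)) stop("map parameters need the image stack")
    nm <- switch(kind, t1_native = "mean_t1_ms", t1_post = "mean_t1post_ms",
                 t2 = "mean_t2_ms")
    out[[nm]] <- map_mean(image, mask)
  } else if (kind == "flow") {
    if (is.null(image)) stop("flow parameters need the velocity stack")
    fl <- flow_amplitudes(image, mask)
    out$net_flow_ml <- fl$net_flow_ml
    out$backward_flow_ml <- fl$backward_flow_ml
  }
  structure(out, class = "cardiac_params")
}

#' @export
print.cardiac_params <- function(x, ...) {
  cat(sprintf("<cardiac_params> kind=%s\n", x$kind))
  for (nm in setdiff(names(x), "kind"))
    cat(sprintf("  %s: %.4g\n", nm, x[[nm]]))
  invisible(x)
}

#' Convert cardiac parameters to a long data.frame
#' @param x a `cardiac_params` object.
#' @param ... unused.
#' @export
as.data.frame.cardiac_params <- function(x, ...) {
  nm <- setdiff(names(x), "kind")
  data.frame(kind = x$kind, parameter = nm,
             value = vapply(nm, function(n) as.numeric(x[[n]]), numeric(1)),
             row.names = NULL)
}
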