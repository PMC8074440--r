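# Synthetic short-axis cardiac phantom with analytically known ground truth.
#
# Geometry: the LV is a stack of disks (cavity) surrounded by annuli
# (myocardium) whose radii taper toward the apex; the RV is a crescent formed
# by a lateral disk minus the LV epicardial disk; LGE scar is an angular wedge
# strictly inside the myocardium; the aorta is a disk carrying a parabolic
# in-plane velocity profile modulated sinusoidally (with offset) in time.
# A voxel belongs to a structure iff its center lies inside the analytic
# shape, so ground-truth volumes are exact voxel counts.

local_seed <- function(seed, code) {
  force(seed)  # a lazily-supplied seed may itself draw from the RNG; force
               # it before the state snapshot or the draw would be undone
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

default_tissue_means <- function(kind) {
  switch(kind,
    cine = c(background = 60, lv_cavity = 180, lv_myo = 90, rv_cavity = 170),
    lge = c(background = 40, lv_cavity = 140, lv_myo = 60, scar = 130),
    t1_native = c(background = 300, lv_cavity = 1600, lv_myo = 1000),
    t1_post = c(background = 300, lv_cavity = 300, lv_myo = 470),
    t2 = c(background = 30, lv_cavity = 240, lv_myo = 50),
    flow = c(background = 0, aorta = NA))  # aorta carries the velocity field
}

default_noise_sd <- function(kind) {
  switch(kind, cine = 8, lge = 8, t1_native = 40, t1_post = 25, t2 = 4, flow = 4)
}

#' Specification of a synthetic cardiac phantom
#'
#' Defaults define the package's reference study conditions: a 64x64 grid at
#' 1.37 mm in-plane (0.78 mm for flow, the typical phase-contrast resolution),
#' 10 slices of which slices 3-9 contain the heart (leaving basal room for
#' the over-segmentation fixtures), 8 mm structural / 10 mm
#' cine slice thickness, an 800 ms cardiac cycle (12 cine frames, 20 flow
#' frames), and tissue means in plausible physical units per sequence kind.
#'
#' @param kind sequence kind, see [SEQUENCE_KINDS].
#' @param n_slices total slice count (temporal flow phantoms use 1 slice).
#' @param grid image grid as (rows, cols).
#' @param in_plane_spacing_mm in-plane pixel spacing (mm).
#' @param slice_thickness_mm slice thickness (mm).
#' @param n_frames frames per cardiac cycle (cine/flow only).
#' @param lv_radius_ed_mm,lv_radius_es_mm basal LV cavity radius at
#'   end-diastole / end-systole (mm). Static kinds use `lv_radius_ed_mm`.
#' @param myo_thickness_mm myocardial wall thickness (mm).
#' @param apex_taper cavity radius multiplier at the most apical active slice
#'   (linear taper from 1 at the base).
#' @param active_slices indices of slices containing the heart.
#' @param center_mm in-plane heart center offset from grid center (mm).
#' @param rv_enabled include an RV crescent (cine only).
#' @param scar_angular_extent_deg,scar_transmurality,scar_start_deg LGE scar
#'   wedge: angular extent, transmural fraction of the wall in (0, 1], start
#'   angle.
#' @param aorta_radius_mm aortic lumen radius (flow).
#' @param v_peak_cm_s peak centerline aortic velocity (cm/s).
#' @param flow_amp,flow_offset temporal velocity modulation
#'   `flow_amp * sin(2*pi*(f-1)/n_frames) + flow_offset`; the default makes a
#'   few late frames net-negative (early diastolic backflow).
#' @param tissue_means named vector of per-structure intensities (arbitrary
#'   units, ms for maps); `NULL` for the documented per-kind defaults.
#' @param noise_sd additive Gaussian intensity noise SD.
#' @param seed integer RNG seed; all phantom output is a pure function of
#'   (spec, seed).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(kind,
                         n_slices = if (kind == "flow") 1L else 10L,
                         grid = c(64L, 64L),
                         in_plane_spacing_mm = if (kind == "flow") 0.78 else 1.37,
                         slice_thickness_mm = if (kind %in% c("cine", "flow")) 10 else 8,
                         n_frames = switch(kind, cine = 12L, flow = 20L, 1L),
                         lv_radius_ed_mm = 17,
                         lv_radius_es_mm = 11,
                         myo_thickness_mm = 6,
                         apex_taper = 0.45,
                         active_slices = if (n_slices >= 5) 3:(n_slices - 1) else seq_len(n_slices),
                         center_mm = c(0, 0),
                         rv_enabled = (kind == "cine"),
                         scar_angular_extent_deg = 90,
                         scar_transmurality = 0.5,
                         scar_start_deg = -45,
                         aorta_radius_mm = 12,
                         v_peak_cm_s = 100,
                         flow_amp = 0.9,
                         flow_offset = 0.35,
                         tissue_means = NULL,
                         noise_sd = NULL,
                         seed = 1L) {
  kind <- as_sequence_kind(kind)
  if (is.null(tissue_means)) tissue_means <- default_tissue_means(kind)
  if (is.null(noise_sd)) noise_sd <- default_noise_sd(kind)
  stopifnot(n_slices >= 1, all(grid >= 8), in_plane_spacing_mm > 0,
            slice_thickness_mm > 0, n_frames >= 1,
            lv_radius_ed_mm > 0, lv_radius_es_mm > 0,
            lv_radius_es_mm < lv_radius_ed_mm || kind != "cine",
            myo_thickness_mm > 0, apex_taper > 0, apex_taper <= 1,
            scar_transmurality > 0, scar_transmurality <= 1,
            noise_sd >= 0)
  structure(list(
    kind = kind, n_slices = as.integer(n_slices), grid = as.integer(grid),
    in_plane_spacing_mm = in_plane_spacing_mm,
    slice_thickness_mm = slice_thickness_mm, n_frames = as.integer(n_frames),
    lv_radius_ed_mm = lv_radius_ed_mm, lv_radius_es_mm = lv_radius_es_mm,
    myo_thickness_mm = myo_thickness_mm, apex_taper = apex_taper,
    active_slices = as.integer(active_slices), center_mm = center_mm,
    rv_enabled = rv_enabled,
    scar_angular_extent_deg = scar_angular_extent_deg,
    scar_transmurality = scar_transmurality, scar_start_deg = scar_start_deg,
    aorta_radius_mm = aorta_radius_mm, v_peak_cm_s = v_peak_cm_s,
    flow_amp = flow_amp, flow_offset = flow_offset,
    tissue_means = tissue_means, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec")
}

# Per-active-slice cavity taper factors (1 at base, apex_taper at apex).
taper_factors <- function(spec) {
  k <- length(spec$active_slices)
  if (k == 1) return(1)
  1 - (1 - spec$apex_taper) * (seq_len(k) - 1) / (k - 1)
}

# Cine cavity-radius schedule over frames: unique maximum at frame 1 (ED)
# and, for even frame counts, unique minimum at frame n/2 + 1 (ES).
radius_schedule <- function(spec) {
  if (spec$kind != "cine") return(rep(spec$lv_radius_ed_mm, spec$n_frames))
  f <- seq_len(spec$n_frames)
  w <- (1 + cos(2 * pi * (f - 1) / spec$n_frames)) / 2
  spec$lv_radius_es_mm + (spec$lv_radius_ed_mm - spec$lv_radius_es_mm) * w
}

#' Basal LV cavity radius giving a target disk-summation volume
#'
#' Inverts the stacked-disk volume formula
#' `V = sum_s pi * (r * taper_s)^2 * thickness` for the basal radius `r`.
#'
#' @param volume_ml target cavity volume in mL.
#' @param spec a [phantom_spec] supplying taper, active slices and thickness.
#' @return basal cavity radius in mm.
#' @export
lv_radius_for_volume <- function(volume_ml, spec) {
  t2 <- sum(taper_factors(spec)^2)
  sqrt(volume_ml * 1000 / (pi * spec$slice_thickness_mm * t2))
}

# Voxel-center coordinate grids (mm), heart-centered.
coord_grids <- function(spec) {
  nr <- spec$grid[1]; nc <- spec$grid[2]; dp <- spec$in_plane_spacing_mm
  x <- (seq_len(nr) - (nr + 1) / 2) * dp - spec$center_mm[1]
  y <- (seq_len(nc) - (nc + 1) / 2) * dp - spec$center_mm[2]
  list(x = matrix(x, nr, nc), y = matrix(y, nr, nc, byrow = TRUE))
}

# Label one 2D slice of the heart for a given cavity radius (mm).
label_slice <- function(spec, g, r_cav, r_rv = NULL) {
  lab <- matrix(0L, spec$grid[1], spec$grid[2])
  r2 <- g$x^2 + g$y^2
  r_epi <- r_cav + spec$myo_thickness_mm
  lab[r2 <= r_epi^2] <- LABELS[["lv_myo"]]
  lab[r2 <= r_cav^2] <- LABELS[["lv_cavity"]]
  if (spec$kind == "lge") {
    th <- atan2(g$y, g$x) * 180 / pi
    rel <- (th - spec$scar_start_deg) %% 360
    r_scar <- r_cav + spec$scar_transmurality * spec$myo_thickness_mm
    sel <- lab == LABELS[["lv_myo"]] & rel <= spec$scar_angular_extent_deg &
      r2 <= r_scar^2
    lab[sel] <- LABELS[["scar"]]
  }
  if (isTRUE(spec$rv_enabled) && !is.null(r_rv) && r_rv > 0) {
    d <- r_epi * 0.9
    rv2 <- g$x^2 + (g$y + d)^2
    sel <- rv2 <= r_rv^2 & r2 > r_epi^2
    lab[sel] <- LABELS[["rv_cavity"]]
  }
  lab
}

intensity_from_labels <- function(spec, lab) {
  tm <- spec$tissue_means
  img <- matrix(tm[["background"]], nrow(lab), ncol(lab))
  nm <- names(LABELS)
  for (l in setdiff(unique(as.integer(lab)), 0L)) {
    key <- nm[match(l, LABELS)]
    img[lab == l] <- tm[[key]]
  }
  img
}

# Faint non-cardiac "ghost" disk on the slice just basal of the heart
# (out-flow-tract-like tissue the network and RF must learn to reject).
ghost_slice_intensity <- function(spec, g) {
  img <- matrix(spec$tissue_means[["background"]], spec$grid[1], spec$grid[2])
  r2 <- g$x^2 + g$y^2
  r <- spec$lv_radius_ed_mm * max(taper_factors(spec)[1], 0.8)
  img[r2 <= (r + spec$myo_thickness_mm)^2] <- 0.55 * spec$tissue_means[["lv_cavity"]]
  img
}

phantom_truth <- function(mask, spec, extra = list()) {
  vv <- voxel_volume_mm3(mask)
  d <- dim(mask$labels)
  nf <- if (length(d) == 4) d[4] else 1L
  labs <- setdiff(kind_labels(spec$kind), 0L)
  vol <- matrix(0, nf, length(labs), dimnames = list(NULL, names(LABELS)[match(labs, LABELS)]))
  for (f in seq_len(nf)) {
    m <- if (length(d) == 4) mask$labels[, , , f] else mask$labels
    for (j in seq_along(labs)) vol[f, j] <- sum(m == labs[j]) * vv / 1000
  }
  tr <- list(mask = mask, volumes_ml = as.data.frame(vol), spec = spec)
  if (spec$kind == "cine") {
    v <- vol[, "lv_cavity"]
    tr$ed_frame <- which.max(v); tr$es_frame <- which.min(v)
    tr$true_lv_ef_pct <- unname(100 * (v[tr$ed_frame] - v[tr$es_frame]) / v[tr$ed_frame])
    if (spec$rv_enabled) {
      rv <- vol[, "rv_cavity"]
      tr$true_rv_ef_pct <- unname(100 * (rv[tr$ed_frame] - rv[tr$es_frame]) / rv[tr$ed_frame])
    }
    tr$true_lv_mass_g <- unname(vol[tr$ed_frame, "lv_myo"] * 1.05)
  }
  if (spec$kind == "lge") {
    tr$true_scar_pct <- unname(100 * vol[1, "scar"] / (vol[1, "lv_myo"] + vol[1, "scar"]))
  }
  if (spec$kind %in% c("t1_native", "t1_post", "t2")) {
    tr$true_map_mean_ms <- unname(spec$tissue_means[["lv_myo"]])
  }
  c(tr, extra)
}

#' Generate a synthetic cardiac phantom
#'
#' Produces a noisy image stack together with its exact ground-truth mask and
#' analytically known clinical parameters. All output is deterministic given
#' the spec (which includes the seed).
#'
#' @param spec a [phantom_spec].
#' @return a list with elements `image` ([cmr_stack]) and `truth` (a list
#'   holding the ground-truth [cmr_mask], per-frame volumes in mL, and the
#'   true clinical parameters for the spec's kind).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$kind == "flow") return(make_flow_phantom(spec))
  g <- coord_grids(spec)
  nr <- spec$grid[1]; nc <- spec$grid[2]
  nf <- if (spec$kind == "cine") spec$n_frames else 1L
  rs <- radius_schedule(spec)
  tf <- taper_factors(spec)
  lab <- array(0L, c(nr, nc, spec$n_slices, nf))
  img <- array(spec$tissue_means[["background"]], c(nr, nc, spec$n_slices, nf))
  # static kinds carry a non-cardiac "ghost" disk just basal of the heart —
  # the tissue the 2D models over-segment and the RF rejector removes; cine
  # has no rejector, so its phantoms keep plain background there
  ghost <- if (spec$kind == "cine") 0L else min(spec$active_slices) - 1L
  for (f in seq_len(nf)) {
    for (j in seq_along(spec$active_slices)) {
      s <- spec$active_slices[j]
      r_cav <- rs[f] * tf[j]
      r_rv <- if (spec$rv_enabled) 0.95 * rs[f] * tf[j] + 4 else NULL
      ls <- label_slice(spec, g, r_cav, r_rv)
      if (sum(ls == LABELS[["lv_myo"]]) + sum(ls == LABELS[["scar"]]) == 0)
        stop(sprintf("geometry leaves zero myocardium voxels on slice %d", s))
      lab[, , s, f] <- ls
      img[, , s, f] <- intensity_from_labels(spec, ls)
    }
    if (ghost >= 1) img[, , ghost, f] <- ghost_slice_intensity(spec, g)
  }
  noisy <- local_seed(spec$seed,
    img + array(rnorm(length(img), 0, spec$noise_sd), dim(img)))
  if (spec$kind != "cine") {
    lab <- array(lab, c(nr, nc, spec$n_slices))
    noisy <- array(noisy, c(nr, nc, spec$n_slices))
  }
  fd <- if (spec$kind == "cine") 800 / spec$n_frames else NULL
  stack <- cmr_stack(noisy, spec$kind, spec$in_plane_spacing_mm,
                     spec$slice_thickness_mm, fd)
  mask <- cmr_mask(lab, spec$kind, spec$in_plane_spacing_mm,
                   spec$slice_thickness_mm, fd)
  list(image = stack, truth = phantom_truth(mask, spec))
}

#' Generate an aortic phase-contrast flow phantom
#'
#' The aorta is a disk with a parabolic through-plane velocity profile
#' `v(r) = v_peak * (1 - (r/R)^2)` modulated in time by
#' `flow_amp * sin(2*pi*(f-1)/n) + flow_offset`, so some frames are
#' net-negative. Ground-truth net and backward flow are computed from the
#' noiseless voxelized velocity field:
#' `Q_f = sum_pixels v * a`, `net = sum_f Q_f dt`,
#' `backward = |sum_f min(Q_f, 0) dt|`.
#'
#' @param spec a [phantom_spec] with `kind = "flow"`.
#' @return as [make_phantom], with `true_net_flow_ml` and
#'   `true_backward_flow_ml` in the truth.
#' @export
make_flow_phantom <- function(spec) {
  stopifnot(spec$kind == "flow")
  g <- coord_grids(spec)
  nr <- spec$grid[1]; nc <- spec$grid[2]
  nf <- spec$n_frames
  r2 <- g$x^2 + g$y^2
  inside <- r2 <= spec$aorta_radius_mm^2
  profile <- spec$v_peak_cm_s * pmax(0, 1 - r2 / spec$aorta_radius_mm^2)
  gmod <- spec$flow_amp * sin(2 * pi * (seq_len(nf) - 1) / nf) + spec$flow_offset
  vel <- array(0, c(nr, nc, 1, nf))
  lab <- array(0L, c(nr, nc, 1, nf))
  for (f in seq_len(nf)) {
    vf <- matrix(0, nr, nc)
    vf[inside] <- profile[inside] * gmod[f]
    vel[, , 1, f] <- vf
    lab[, , 1, f] <- ifelse(inside, LABELS[["aorta"]], 0L)
  }
  a_mm2 <- spec$in_plane_spacing_mm^2
  dt_s <- (800 / nf) / 1000
  q_mm3_s <- vapply(seq_len(nf),
                    function(f) sum(vel[, , 1, f][inside]) * 10 * a_mm2,
                    numeric(1))
  net_ml <- sum(q_mm3_s) * dt_s / 1000
  back_ml <- abs(sum(pmin(q_mm3_s, 0)) * dt_s / 1000)
  noisy <- local_seed(spec$seed,
    vel + array(rnorm(length(vel), 0, spec$noise_sd), dim(vel)))
  fd <- 800 / nf
  stack <- cmr_stack(noisy, "flow", spec$in_plane_spacing_mm,
                     spec$slice_thickness_mm, fd)
  mask <- cmr_mask(lab, "flow", spec$in_plane_spacing_mm,
                   spec$slice_thickness_mm, fd)
  truth <- phantom_truth(mask, spec,
                         extra = list(true_net_flow_ml = net_ml,
                                      true_backward_flow_ml = back_ml,
                                      frame_flow_mm3_s = q_mm3_s))
  list(image = stack, truth = truth)
}

#' Build an over-segmentation fixture
#'
#' Returns a static-kind phantom whose `corrupted` mask equals the ground
#' truth plus plausible LV labels (cavity disk + myocardial ring) on
#' `n_extra` slices beyond the true basal extent, painted over the
#' non-cardiac ghost tissue present in the image there — the failure mode the
#' random-forest slice rejector is trained to remove.
#'
#' @param spec a [phantom_spec] of a static kind (lge or a map).
#' @param n_extra number of spurious basal slices (0 returns an uncorrupted
#'   copy).
#' @return list with `image`, `truth` (as [make_phantom]) and `corrupted`
#'   ([cmr_mask]).
#' @export
make_oversegmentation_fixture <- function(spec, n_extra = 1L) {
  stopifnot(inherits(spec, "phantom_spec"),
            !spec$kind %in% c("cine", "flow"), n_extra >= 0)
  ph <- make_phantom(spec)
  avail <- min(spec$active_slices) - 1L
  if (n_extra > avail)
    stop(sprintf("n_extra = %d exceeds the %d empty basal slice(s)", n_extra, avail))
  lab <- ph$truth$mask$labels
  if (n_extra > 0) {
    g <- coord_grids(spec)
    r_cav <- 0.9 * spec$lv_radius_ed_mm * taper_factors(spec)[1]
    fake_spec <- spec; fake_spec$kind <- "t1_native"  # plain LV ring, no scar/RV
    fake <- label_slice(fake_spec, g, r_cav)
    for (s in seq(avail, by = -1L, length.out = n_extra)) lab[, , s] <- fake
  }
  corrupted <- cmr_mask(lab, spec$kind, spec$in_plane_spacing_mm,
                        spec$slice_thickness_mm)
  c(ph, list(corrupted = corrupted, n_extra = as.integer(n_extra)))
}

#' Draw a randomized phantom spec (population variability)
#'
#' Jitters heart geometry, intensities and noise around the reference
#' conditions so that training and evaluation phantoms differ, emulating
#' between-subject variability.
#'
#' @param kind sequence kind.
#' @param seed integer seed (also becomes the phantom's noise seed).
#' @param ... overrides forwarded to [phantom_spec].
#' @return a [phantom_spec].
#' @export
sample_phantom_spec <- function(kind, seed, ...) {
  kind <- as_sequence_kind(kind)
  local_seed(seed, {
    r_ed <- runif(1, 14, 19)
    r_es <- r_ed * runif(1, 0.55, 0.70)
    tm <- default_tissue_means(kind)
    jit <- function(x) x * runif(length(x), 0.92, 1.08)
    if (kind != "flow") tm[] <- jit(tm)
    phantom_spec(kind,
                 lv_radius_ed_mm = r_ed, lv_radius_es_mm = r_es,
                 myo_thickness_mm = runif(1, 5, 7),
                 apex_taper = runif(1, 0.4, 0.55),
                 center_mm = runif(2, -3, 3),
                 aorta_radius_mm = runif(1, 10, 14),
                 v_peak_cm_s = runif(1, 80, 120),
                 scar_angular_extent_deg = runif(1, 60, 140),
                 scar_transmurality = runif(1, 0.35, 0.8),
                 scar_start_deg = runif(1, -180, 180),
                 tissue_means = tm,
                 seed = sample.int(2^31 - 2, 1),
                 ...)
  })
}
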