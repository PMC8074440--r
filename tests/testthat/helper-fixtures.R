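# Small, fast phantom specs shared across tests; full-size study conditions
# are exercised in test-acceptance.R.

tiny_spec <- function(kind, ...) {
  phantom_spec(kind,
               n_slices = if (kind == "flow") 1L else 6L,
               grid = c(32L, 32L),
               n_frames = switch(kind, cine = 6L, flow = 12L, 1L),
               lv_radius_ed_mm = 9, lv_radius_es_mm = 6,
               myo_thickness_mm = 4, aorta_radius_mm = 8,
               ...)
}

# Brute-force metric oracles on small masks (voxel-set arithmetic only;
# independent of the package's surface-extraction implementation path).
oracle_dice <- function(a, b, label) {
  ai <- which(a == label); bi <- which(b == label)
  if (length(ai) + length(bi) == 0) return(1)
  2 * length(intersect(ai, bi)) / (length(ai) + length(bi))
}

oracle_boundary <- function(vol, label) {
  idx <- which(vol == label, arr.ind = TRUE)
  d <- dim(vol)
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c <- idx[i, 2]; s <- idx[i, 3]
    nb <- rbind(c(r - 1, c, s), c(r + 1, c, s), c(r, c - 1, s),
                c(r, c + 1, s), c(r, c, s - 1), c(r, c, s + 1))
    for (j in 1:6) {
      p <- nb[j, ]
      if (any(p < 1) || any(p > d)) { keep[i] <- TRUE; break }
      if (vol[p[1], p[2], p[3]] != label) { keep[i] <- TRUE; break }
    }
  }
  idx[keep, , drop = FALSE]
}

oracle_surface <- function(a, b, label, spacing) {
  pa <- oracle_boundary(a, label); pb <- oracle_boundary(b, label)
  if (nrow(pa) == 0 || nrow(pb) == 0) return(list(hd = NA, msd = NA))
  sa <- sweep(pa, 2, spacing, `*`); sb <- sweep(pb, 2, spacing, `*`)
  dm <- outer(seq_len(nrow(sa)), seq_len(nrow(sb)), Vectorize(function(i, j)
    sqrt(sum((sa[i, ] - sb[j, ])^2))))
  dab <- apply(dm, 1, min); dba <- apply(dm, 2, min)
  list(hd = max(max(dab), max(dba)), msd = (mean(dab) + mean(dba)) / 2)
}

random_blob_pair <- function(seed, d = c(8L, 8L, 5L), label = 1L) {
  set.seed(seed)
  mk <- function() {
    v <- array(0L, d)
    ctr <- c(runif(1, 2, d[1] - 1), runif(1, 2, d[2] - 1), runif(1, 1.5, d[3] - 0.5))
    rad <- runif(1, 1.2, 3)
    for (s in seq_len(d[3])) for (r in seq_len(d[1])) for (c in seq_len(d[2]))
      if (sum(((c(r, c, s) - ctr) / c(1, 1, 1.5))^2) <= rad^2) v[r, c, s] <- label
    if (sum(v) == 0) v[ceiling(d[1] / 2), ceiling(d[2] / 2), 1] <- label
    v
  }
  list(a = mk(), b = mk())
}
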