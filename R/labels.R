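#' Anatomical label codebook
#'
#' Fixed integer codes used by every stage of the pipeline. The codebook is
#' the single source of truth: no stage may emit labels outside it.
#'
#' @format Named integer vector: background 0, LV cavity 1, LV myocardium 2,
#'   RV cavity 3, scar 4, aorta 5.
#' @export
LABELS <- c(background = 0L, lv_cavity = 1L, lv_myo = 2L,
            rv_cavity = 3L, scar = 4L, aorta = 5L)

#' Supported CMR sequence kinds
#' @export
SEQUENCE_KINDS <- c("cine", "lge", "t1_native", "t1_post", "t2", "flow")

#' Validate and normalize a sequence kind
#' @param kind character scalar, one of [SEQUENCE_KINDS].
#' @return the matched kind.
#' @export
as_sequence_kind <- function(kind) {
  match.arg(kind, SEQUENCE_KINDS)
}

#' Legal label set for a sequence kind
#'
#' Cine stacks carry LV cavity, myocardium and RV cavity; LGE additionally
#' carries scar (but no RV); relaxation maps carry LV cavity and myocardium
#' only; flow images carry only the aorta.
#'
#' @param kind a sequence kind.
#' @return integer vector of legal label codes (background first).
#' @export
kind_labels <- function(kind) {
  kind <- as_sequence_kind(kind)
  switch(kind,
    cine = c(0L, 1L, 2L, 3L),
    lge = c(0L, 1L, 2L, 4L),
    t1_native = ,
    t1_post = ,
    t2 = c(0L, 1L, 2L),
    flow = c(0L, 5L))
}

#' Number of segmentation classes for a sequence kind
#' @inheritParams kind_labels
#' @return integer class count (cine/LGE 4, maps 3, flow 2).
#' @export
kind_n_classes <- function(kind) length(kind_labels(kind))

#' Does the sequence kind have a temporal axis?
#' @inheritParams kind_labels
#' @export
kind_is_temporal <- function(kind) as_sequence_kind(kind) %in% c("cine", "flow")

#' Intensity units carried by a sequence kind
#' @inheritParams kind_labels
#' @return "milliseconds" for relaxation maps, "cm_per_s" for flow phase
#'   images, "arbitrary" otherwise.
#' @export
kind_units <- function(kind) {
  kind <- as_sequence_kind(kind)
  if (kind %in% c("t1_native", "t1_post", "t2")) return("milliseconds")
  if (kind == "flow") return("cm_per_s")
  "arbitrary"
}

check_labels_legal <- function(labels, kind) {
  legal <- kind_labels(kind)
  bad <- setdiff(unique(as.integer(labels)), legal)
  if (length(bad) > 0) {
    stop(sprintf("illegal label(s) %s for kind '%s' (legal: %s)",
                 paste(bad, collapse = ", "), kind,
                 paste(legal, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
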