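# Study-level batch processing: run every manifest entry end-to-end,
# tabulate parameters, flag physiological-range outliers for human review,
# and quantify confidence against corrected analyses.

#' Default physiological plausibility ranges
#'
#' Shipped conventions for flagging, editable per study (see
#' [read_physio_ranges()]); these are review triggers, not normal ranges.
#'
#' @return named list of inclusive `c(low, high)` bounds per parameter.
#' @export
default_physio_ranges <- function() {
  read_physio_ranges(system.file("extdata", "physio_ranges.yaml",
                                 package = "cmrpipe"))
}

#' Read physiological ranges from a YAML file
#' @param path YAML file mapping parameter names to `[low, high]` pairs.
#' @export
read_physio_ranges <- function(path) {
  r <- yaml::read_yaml(path)
  for (nm in names(r)) {
    b <- as.numeric(r[[nm]])
    if (length(b) != 2 || !(b[1] < b[2]))
      stop(sprintf("range for '%s' must be [low, high] with low < high", nm))
    r[[nm]] <- b
  }
  r
}

flag_outliers <- function(params_df, ranges) {
  rows <- list()
  for (i in seq_len(nrow(params_df))) {
    p <- params_df$parameter[i]
    if (is.null(ranges[[p]])) next
    b <- ranges[[p]]
    v <- params_df$value[i]
    if (is.finite(v) && (v < b[1] || v > b[2]))
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = params_df$subject_id[i], kind = params_df$kind[i],
        parameter = p, value = v, low = b[1], high = b[2])
  }
  if (length(rows) == 0)
    return(data.frame(subject_id = character(), kind = character(),
                      parameter = character(), value = numeric(),
                      low = numeric(), high = numeric()))
  do.call(rbind, rows)
}

#' Run a full study from a manifest
#'
#' Processes each subject/sequence entry: images are segmented with the
#' supplied per-kind models (and optional rejectors), or — when the manifest
#' provides `mask_path` and no model covers the kind — analyzed from the
#' stored masks. Clinical parameters are tabulated and values outside the
#' physiological ranges flagged. Per-subject failures are logged and skipped;
#' they never abort the batch.
#'
#' @param manifest path to a manifest CSV or a data.frame from
#'   [read_manifest()].
#' @param models named list of trained `unet_model`s by kind (optional).
#' @param rejectors named list of `slice_rejector`s by kind (optional).
#' @param ranges physiological ranges (default [default_physio_ranges()]).
#' @param out_dir optional directory for `report.csv`, `flags.csv` and
#'   `run.log`.
#' @return a `study_report` list with `params` (long data.frame), `flags`,
#'   and `failures`.
#' @export
run_study <- function(manifest, models = NULL, rejectors = NULL,
                      ranges = default_physio_ranges(), out_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  params <- list(); failures <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      stack <- read_stack(row$image_path, row$kind)
      mask <- if (!is.null(models[[row$kind]])) {
        segment_stack(models[[row$kind]], stack,
                      rejector = rejectors[[row$kind]])$mask
      } else if (!is.na(row$mask_path)) {
        read_mask(row$mask_path, row$kind)
      } else {
        stop(sprintf("no model and no mask for kind '%s'", row$kind))
      }
      p <- as.data.frame(extract_params(mask, image = stack))
      p$subject_id <- row$subject_id
      p
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- data.frame(
        subject_id = row$subject_id, kind = row$kind,
        message = conditionMessage(res))
    } else {
      params[[length(params) + 1]] <- res
    }
  }
  params_df <- if (length(params)) do.call(rbind, params) else
    data.frame(kind = character(), parameter = character(),
               value = numeric(), subject_id = character())
  params_df <- params_df[, c("subject_id", "kind", "parameter", "value")]
  failures_df <- if (length(failures)) do.call(rbind, failures) else
    data.frame(subject_id = character(), kind = character(),
               message = character())
  report <- structure(list(params = params_df,
                           flags = flag_outliers(params_df, ranges),
                           failures = failures_df),
                      class = "study_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(report$params, file.path(out_dir, "report.csv"), row.names = FALSE)
    write.csv(report$flags, file.path(out_dir, "flags.csv"), row.names = FALSE)
    writeLines(sprintf("processed=%d failed=%d flagged=%d",
                       length(unique(report$params$subject_id)),
                       nrow(report$failures), nrow(report$flags)),
               file.path(out_dir, "run.log"))
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d parameter rows, %d flags, %d failures\n",
              nrow(x$params), nrow(x$flags), nrow(x$failures)))
  invisible(x)
}

percentage_params <- c("lv_ef_pct", "rv_ef_pct", "scar_pct")

#' Confidence of automatic measurements against corrected analyses
#'
#' For each parameter present in both reports (>= 3 paired subjects),
#' computes [agreement()] between the automatic and corrected values — the
#' global-confidence indicator for a study. EF and scar percentage use the
#' absolute-difference rule; all other parameters the relative rule.
#'
#' @param auto_report,corrected_report `study_report`s (or their `params`
#'   data.frames) sharing subjects.
#' @return data.frame with one agreement row per parameter.
#' @export
confidence <- function(auto_report, corrected_report) {
  a <- if (inherits(auto_report, "study_report")) auto_report$params else auto_report
  b <- if (inherits(corrected_report, "study_report")) corrected_report$params else corrected_report
  merged <- merge(a, b, by = c("subject_id", "kind", "parameter"),
                  suffixes = c("_auto", "_ref"))
  out <- list()
  for (p in unique(merged$parameter)) {
    sub <- merged[merged$parameter == p, ]
    if (nrow(sub) < 3) next
    kind <- if (p %in% percentage_params) "percentage" else "numerical"
    st <- agreement(sub$value_auto, sub$value_ref, kind)
    st$parameter <- p
    out[[length(out) + 1]] <- st
  }
  if (length(out) == 0) stop("no parameter has at least 3 paired values")
  do.call(rbind, out)
}
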