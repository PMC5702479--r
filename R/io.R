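# Tabular readers/writers. All tables are tab-delimited with headers; TR
# indices on disk are 0-based.

#' Write a multi-subject ROI time-series set
#'
#' One file per subject per run (`sub-XX_run-YY_timeseries.tsv`; rows = TRs,
#' columns = ROIs), plus a `timeseries_index.json` sidecar recording ROI
#' names, TR, run lengths and stage.
#'
#' @param series a [roi_ts()] object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_roi_ts <- function(series, dir) {
  stopifnot(inherits(series, "roi_ts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  S <- dim(series$data)[1]
  run_idx <- .run_index_list(series$run_lens)
  for (s in seq_len(S)) {
    for (r in seq_along(run_idx)) {
      M <- t(series$data[s, , run_idx[[r]], drop = TRUE])
      colnames(M) <- series$rois
      f <- file.path(dir, sprintf("sub-%02d_run-%02d_timeseries.tsv", s, r))
      utils::write.table(M, f, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(
    list(n_subjects = S, rois = series$rois, tr = series$tr,
         run_lens = series$run_lens, stage = series$stage),
    file.path(dir, "timeseries_index.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a ROI time-series set written by [write_roi_ts()]
#'
#' @param dir directory containing the per-subject files and sidecar.
#' @return a [roi_ts()] object.
#' @export
read_roi_ts <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "timeseries_index.json"),
                              simplifyVector = TRUE)
  S <- meta$n_subjects
  run_lens <- as.integer(meta$run_lens)
  T_all <- sum(run_lens)
  R <- length(meta$rois)
  data <- array(NA_real_, c(S, R, T_all))
  run_idx <- .run_index_list(run_lens)
  for (s in seq_len(S)) {
    for (r in seq_along(run_lens)) {
      f <- file.path(dir, sprintf("sub-%02d_run-%02d_timeseries.tsv", s, r))
      if (!file.exists(f)) stop("missing input file: ", f)
      M <- utils::read.table(f, header = TRUE, sep = "\t",
                             check.names = FALSE)
      data[s, , run_idx[[r]]] <- t(as.matrix(M))
    }
  }
  roi_ts(data, meta$rois, meta$tr, run_lens, stage = meta$stage)
}

#' Write an ISM as a square table with ROI header row and column
#' @param ism an `ism` matrix.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_ism <- function(ism, file) {
  M <- as.data.frame(unclass(ism))
  utils::write.table(cbind(roi = rownames(ism), M), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read an ISM written by [write_ism()]
#' @param file path to the square table.
#' @param kind,symmetric,sample_count metadata to re-attach.
#' @return an `ism` matrix.
#' @export
read_ism <- function(file, kind = "group", symmetric = TRUE,
                     sample_count = NA_integer_) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         check.names = FALSE)
  rois <- d$roi
  M <- as.matrix(d[, -1, drop = FALSE])
  .new_ism(M, rois, kind, symmetric, sample_count)
}

#' Write condition labels as a TSV (run, TR_index, label, reason)
#' @param labels a `condition_labels` object.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_labels <- function(labels, file) {
  out <- data.frame(run = labels$run, TR_index = labels$tr_index,
                    label = labels$label,
                    reason = ifelse(is.na(labels$reason), "",
                                    labels$reason))
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Serialize a segment index (segments and slices) as JSON
#'
#' Slice TR indices are written 0-based.
#'
#' @param seg a [build_slices()] object.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_segment_index <- function(seg, file) {
  slices0 <- lapply(seg$slices, function(cond) {
    lapply(cond, function(idx) idx - 1L)
  })
  jsonlite::write_json(
    list(segments = seg$segments, lag_s = seg$lag_s,
         min_samples = seg$min_samples, tr = seg$tr, slices = slices0),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write weight trajectories as long-format TSV
#' @param traj trajectory tibble (optionally with corrected weights).
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_weights <- function(traj, file) {
  utils::write.table(traj, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
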