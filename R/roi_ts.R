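#' Multi-subject ROI time-series container
#'
#' Holds the subjects x ROIs x TRs array of a multi-run acquisition together
#' with run boundaries and a processing-stage flag. Runs are contiguous TR
#' spans; TR indices in on-disk tables are 0-based, while in-memory indexing
#' follows R's 1-based convention.
#'
#' @param data numeric array, subjects x ROIs x TRs.
#' @param rois character vector of ROI names (length = dim 2).
#' @param tr repetition time in seconds.
#' @param run_lens integer vector of TRs per run; must sum to dim 3.
#' @param stage processing stage: "raw", "residual" or "zscored".
#' @param motion optional list (one per subject) of TRs x 6 motion-parameter
#'   matrices, concatenated across runs.
#' @return an object of class `roi_ts`.
#' @export
roi_ts <- function(data, rois, tr, run_lens, stage = "raw", motion = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  stopifnot(length(rois) == dim(data)[2])
  stopifnot(sum(run_lens) == dim(data)[3])
  stage <- match.arg(stage, c("raw", "residual", "zscored"))
  dimnames(data) <- list(NULL, rois, NULL)
  structure(
    list(data = data, rois = rois, tr = tr,
         run_lens = as.integer(run_lens), stage = stage, motion = motion),
    class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  d <- dim(x$data)
  cat("<roi_ts> ", d[1], " subjects x ", d[2], " ROIs x ", d[3],
      " TRs (", length(x$run_lens), " runs, TR = ", x$tr, " s, stage = ",
      x$stage, ")\n", sep = "")
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$data)

# 1-based start index of each run
.run_starts <- function(x) cumsum(c(1L, utils::head(x$run_lens, -1)))

# list mapping run -> 1-based TR indices
.run_index_list <- function(run_lens) {
  starts <- cumsum(c(1L, utils::head(run_lens, -1)))
  Map(function(s, l) seq.int(s, length.out = l), starts, run_lens)
}
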