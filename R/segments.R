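#' Extract contiguous approach/retreat segments
#'
#' A segment is a maximal run of consecutive TRs sharing the same
#' non-excluded label. Any excluded TR, and any run boundary, terminates a
#' segment.
#'
#' @param labels a [label_conditions()] object (or a tibble with columns
#'   `run`, `tr_index`, `label` ordered by run and TR).
#' @return tibble with columns `condition`, `run`, `start_tr` (0-based
#'   within run), `start_global` (0-based across the concatenated
#'   experiment), `length`.
#' @export
extract_segments <- function(labels) {
  stopifnot(all(c("run", "tr_index", "label") %in% names(labels)))
  labels <- labels[order(labels$run, labels$tr_index), ]
  vols <- vapply(split(labels$tr_index, labels$run), length, integer(1))
  run0 <- min(labels$run)
  offs <- cumsum(c(0L, utils::head(unname(vols), -1)))
  names(offs) <- names(vols)
  lab <- labels$label
  # break runs of equal labels also at run boundaries
  keygrp <- paste(lab, labels$run)
  r <- rle(keygrp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- lab[starts] %in% c("approach", "retreat")
  if (!any(keep)) {
    return(tibble::tibble(condition = character(0), run = integer(0),
                          start_tr = integer(0), start_global = integer(0),
                          length = integer(0)))
  }
  starts <- starts[keep]; lens <- r$lengths[keep]
  tibble::tibble(
    condition = lab[starts],
    run = labels$run[starts],
    start_tr = labels$tr_index[starts],
    start_global = unname(offs[as.character(labels$run[starts])]) +
      labels$tr_index[starts],
    length = as.integer(lens))
}

#' Build per-time-slice sample indices for dynamic ISC
#'
#' For each condition, the slice at within-segment time `t` (in TR steps
#' after discarding the first `lag_s` seconds of every segment) collects the
#' corresponding TR from every segment long enough to contain it. Slices
#' supported by fewer than `min_samples` segments are dropped. The discarded
#' lag accounts for the hemodynamic delay between condition onset and the
#' BOLD response.
#'
#' @param segments segment table from [extract_segments()].
#' @param lag_s trimmed seconds at each segment start. Default 5.
#' @param min_samples minimum segments per retained slice. Default 20; must
#'   be at least 2 (a correlation over fewer samples is undefined).
#' @param tr repetition time in seconds. Default 1. Slice times advance in
#'   TR steps and are reported in seconds (`t * tr`).
#' @return an object of class `segment_index`: list with `segments`,
#'   `lag_s`, `min_samples`, `tr`, and `slices` -- a named list per
#'   condition, each a list of 1-based global TR index vectors named by the
#'   slice time in seconds.
#' @export
build_slices <- function(segments, lag_s = 5, min_samples = 20, tr = 1) {
  if (min_samples < 2) {
    stop("parameter error: min_samples must be at least 2")
  }
  stopifnot(lag_s >= 0, tr > 0)
  lag <- as.integer(round(lag_s / tr))
  slices <- list()
  for (cond in c("approach", "retreat")) {
    seg <- segments[segments$condition == cond, ]
    out <- list()
    t <- 0L
    repeat {
      ok <- seg$length >= lag + t + 1L
      if (sum(ok) < min_samples) break
      # +1: convert the 0-based global start to a 1-based R index
      out[[as.character(t * tr)]] <- seg$start_global[ok] + lag + t + 1L
      t <- t + 1L
    }
    slices[[cond]] <- out
  }
  structure(list(segments = segments, lag_s = lag_s,
                 min_samples = min_samples, tr = tr, slices = slices),
            class = "segment_index")
}

#' @export
print.segment_index <- function(x, ...) {
  cat("<segment_index> lag ", x$lag_s, " s, min_samples ", x$min_samples,
      "\n", sep = "")
  for (cond in names(x$slices)) {
    ns <- vapply(x$slices[[cond]], length, integer(1))
    cat("  ", cond, ": ", length(ns), " slices",
        if (length(ns)) paste0(" (t = ", names(ns)[1], "..",
                               names(ns)[length(ns)], " s, n = ",
                               paste(ns, collapse = "/"), ")"), "\n",
        sep = "")
  }
  invisible(x)
}
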