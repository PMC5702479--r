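# --- core numerics ----------------------------------------------------------

# standardize rows to mean 0 / unit SD; rows with zero variance become NA
.std_rows <- function(M) {
  n <- ncol(M)
  mu <- rowMeans(M)
  X <- M - mu
  ss <- sqrt(rowSums(X^2) / (n - 1))
  bad <- ss <= 0 | !is.finite(ss)
  ss[bad] <- 1
  X <- X / ss
  X[bad, ] <- NA_real_
  X
}

# leave-one-out ISM for one subject, given this subject's R x n slice data
# and the sum over all subjects' slice data
.ism_one <- function(Ys, total, S) {
  n <- ncol(Ys)
  A <- .std_rows(Ys)
  B <- .std_rows((total - Ys) / (S - 1))
  tcrossprod(A, B) / (n - 1)
}

# group ISM over a list of per-subject R x n matrices: leave-one-out ISMs,
# averaged with pairwise NA deletion, then transpose-symmetrized
.ism_group_core <- function(Ymats) {
  S <- length(Ymats)
  total <- Reduce(`+`, Ymats)
  R <- nrow(Ymats[[1]])
  Gsum <- matrix(0, R, R)
  Gcnt <- matrix(0L, R, R)
  n_undef <- 0L
  for (s in seq_len(S)) {
    M <- .ism_one(Ymats[[s]], total, S)
    ok <- !is.na(M)
    n_undef <- n_undef + sum(!ok)
    M[!ok] <- 0
    Gsum <- Gsum + M
    Gcnt <- Gcnt + ok
  }
  G <- Gsum / Gcnt
  G[Gcnt == 0L] <- NA_real_
  # transpose-average; where one orientation is undefined, keep the other
  A <- G; B <- t(G)
  W <- (!is.na(A)) + (!is.na(B))
  A[is.na(A)] <- 0; B[is.na(B)] <- 0
  sym <- (A + B) / W
  sym[W == 0] <- NA_real_
  list(matrix = sym, n_undefined = n_undef)
}

.subject_mats <- function(series, sample_index) {
  S <- dim(series$data)[1]
  lapply(seq_len(S), function(s) {
    M <- series$data[s, , sample_index, drop = FALSE]
    dim(M) <- dim(M)[2:3]
    rownames(M) <- series$rois
    M
  })
}

.new_ism <- function(mat, rois, kind, symmetric, sample_count,
                     condition = NA_character_, t = NA_real_,
                     n_undefined = 0L) {
  dimnames(mat) <- list(rois, rois)
  structure(mat, class = c("ism", "matrix"), kind = kind,
            symmetric = symmetric, sample_count = sample_count,
            condition = condition, t = t, n_undefined = n_undefined)
}

#' @export
print.ism <- function(x, ...) {
  cat("<ism> ", nrow(x), " x ", ncol(x), " (", attr(x, "kind"),
      if (isTRUE(attr(x, "symmetric"))) ", symmetric",
      "), n = ", attr(x, "sample_count"),
      if (!is.na(attr(x, "condition")))
        paste0(", ", attr(x, "condition"), " t = ", attr(x, "t"), " s"),
      "\n", sep = "")
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

# --- public operations ------------------------------------------------------

#' Leave-one-out intersubject correlation matrix for one subject
#'
#' Entry (i, j) is the Pearson correlation, over the TRs in `sample_index`,
#' between the held-out subject's ROI-i series and the unweighted average of
#' all other subjects' ROI-j series. The diagonal is a cross-brain
#' correlation of a region with itself and is not forced to 1. Entries whose
#' underlying vectors have zero variance over the sample index are returned
#' as `NA` (never silently 0).
#'
#' @param series a z-scored [roi_ts()] object with at least 3 subjects.
#' @param subject 1-based subject index to hold out.
#' @param sample_index 1-based global TR indices to correlate over (>= 2).
#' @return an `ism` matrix, kind "subject".
#' @export
ism_subject <- function(series, subject, sample_index) {
  stopifnot(inherits(series, "roi_ts"))
  S <- dim(series$data)[1]
  if (S < 3) stop("need at least 3 subjects")
  if (length(sample_index) < 2) stop("need at least 2 samples")
  if (series$stage != "zscored") {
    warning("series stage is '", series$stage,
            "'; ISC is defined on z-scored residuals")
  }
  Ymats <- .subject_mats(series, sample_index)
  total <- Reduce(`+`, Ymats)
  M <- .ism_one(Ymats[[subject]], total, S)
  .new_ism(M, series$rois, "subject", FALSE, length(sample_index),
           n_undefined = sum(is.na(M)))
}

#' Group intersubject correlation matrix
#'
#' Averages per-subject leave-one-out ISMs (arithmetic mean of raw Pearson
#' correlations; undefined entries are excluded pairwise, with the count
#' recorded) and symmetrizes the result by averaging with its transpose.
#'
#' @param isms list of >= 3 subject `ism` matrices with matching ROI sets,
#'   as produced by [ism_subject()].
#' @param fisher average on the Fisher-z scale and transform back. Default
#'   `FALSE`: intersubject correlations are small and near-Gaussian, so raw
#'   averaging is used as the primary path.
#' @return an `ism` matrix, kind "group", exactly symmetric.
#' @export
ism_group <- function(isms, fisher = FALSE) {
  stopifnot(length(isms) >= 3)
  rois <- rownames(isms[[1]])
  for (m in isms) {
    if (!identical(rownames(m), rois)) stop("ROI mismatch across subjects")
  }
  R <- length(rois)
  Gsum <- matrix(0, R, R); Gcnt <- matrix(0L, R, R); n_undef <- 0L
  for (m in isms) {
    M <- unclass(m)
    if (fisher) M <- atanh(pmin(pmax(M, -1 + 1e-12), 1 - 1e-12))
    ok <- !is.na(M)
    n_undef <- n_undef + sum(!ok)
    M[!ok] <- 0
    Gsum <- Gsum + M
    Gcnt <- Gcnt + ok
  }
  G <- Gsum / Gcnt
  G[Gcnt == 0L] <- NA_real_
  if (fisher) G <- tanh(G)
  A <- G; B <- t(G)
  W <- (!is.na(A)) + (!is.na(B))
  A[is.na(A)] <- 0; B[is.na(B)] <- 0
  sym <- (A + B) / W
  sym[W == 0] <- NA_real_
  .new_ism(sym, rois, "group", TRUE,
           attr(isms[[1]], "sample_count"), n_undefined = n_undef)
}

#' Dynamic (per-time-slice) group intersubject correlation matrices
#'
#' Computes the group ISM separately for every usable time slice of each
#' condition, using the slice's TR indices.
#'
#' @param series a z-scored [roi_ts()] object.
#' @param seg a [build_slices()] segment index.
#' @return named list (`approach`, `retreat`) of lists of group `ism`
#'   matrices ordered by slice time; each carries its condition, time tag
#'   and sample count. Empty (with a warning) when no slice is usable.
#' @export
ism_dynamic <- function(series, seg) {
  stopifnot(inherits(series, "roi_ts"), inherits(seg, "segment_index"))
  if (all(vapply(seg$slices, length, integer(1)) == 0)) {
    warning("no usable slices")
    return(list(approach = list(), retreat = list()))
  }
  out <- list()
  for (cond in names(seg$slices)) {
    isms <- list()
    for (tname in names(seg$slices[[cond]])) {
      idx <- seg$slices[[cond]][[tname]]
      core <- .ism_group_core(.subject_mats(series, idx))
      isms[[tname]] <- .new_ism(core$matrix, series$rois, "group", TRUE,
                                length(idx), condition = cond,
                                t = as.numeric(tname),
                                n_undefined = core$n_undefined)
    }
    out[[cond]] <- isms
  }
  out
}
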