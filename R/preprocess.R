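#' Build the per-run nuisance design
#'
#' The design for each run contains a constant, orthogonal polynomial drift
#' terms up to `poly_order`, the block boxcar convolved with the hemodynamic
#' response, and (when motion parameters are supplied) the 6 motion
#' parameters and their discrete temporal derivatives (first differences,
#' zero-padded at the run start).
#'
#' @param schedule an [build_schedule()] object.
#' @param motion optional motion parameters: a matrix/data frame with
#'   `schedule$total_vols` rows and 6 columns, or a list of per-run matrices.
#' @param poly_order polynomial drift order per run. Default 4.
#' @param hrf_peak,hrf_undershoot,hrf_ratio HRF shape, see
#'   [hrf_double_gamma()].
#' @return an object of class `nuisance_model`: list with `design`
#'   (per-run design matrices with named columns) and the schedule.
#' @export
build_nuisance <- function(schedule, motion = NULL, poly_order = 4,
                           hrf_peak = 6, hrf_undershoot = 16,
                           hrf_ratio = 1 / 6) {
  stopifnot(inherits(schedule, "event_schedule"), poly_order >= 0)
  L <- schedule$vols_per_run
  kern <- hrf_kernel(schedule$tr, peak = hrf_peak,
                     undershoot = hrf_undershoot, ratio = hrf_ratio)
  if (!is.null(motion) && !is.list(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != schedule$total_vols || ncol(motion) != 6) {
      stop("alignment error: motion table must be total_vols x 6")
    }
    motion <- lapply(.run_index_list(rep(L, schedule$n_runs)),
                     function(idx) motion[idx, , drop = FALSE])
  }
  if (is.list(motion) && length(motion) != schedule$n_runs) {
    stop("alignment error: need one motion matrix per run")
  }
  tt <- (seq_len(L) - 1) * schedule$tr
  boxcar <- as.numeric(!is.na(.block_of_tr(schedule, seq_len(L) - 1L)))
  block_reg <- .convolve_causal(boxcar, kern)
  block_reg <- block_reg / max(abs(block_reg))
  designs <- vector("list", schedule$n_runs)
  for (r in seq_len(schedule$n_runs)) {
    X <- cbind(constant = rep(1, L))
    if (poly_order > 0) {
      P <- stats::poly(tt, degree = poly_order)
      colnames(P) <- paste0("poly", seq_len(poly_order))
      X <- cbind(X, P)
    }
    X <- cbind(X, block = block_reg)
    if (!is.null(motion)) {
      M <- as.matrix(motion[[r]])
      if (nrow(M) != L || ncol(M) != 6) {
        stop("alignment error: motion matrix for run ", r, " must be ",
             L, " x 6")
      }
      colnames(M) <- paste0("motion", 1:6)
      D <- apply(M, 2, function(col) c(0, diff(col)))
      colnames(D) <- paste0("dmotion", 1:6)
      X <- cbind(X, M, D)
    }
    designs[[r]] <- X
  }
  structure(list(design = designs, schedule = schedule,
                 poly_order = poly_order),
            class = "nuisance_model")
}

#' Regress nuisance terms out of ROI time series and z-score per run
#'
#' Ordinary least-squares residualization of every subject x ROI x run series
#' against the run's nuisance design, followed (by default) by z-scoring of
#' each run's residual series. Residuals are exactly orthogonal to every
#' design column.
#'
#' @param series a raw [roi_ts()] object.
#' @param model a [build_nuisance()] model; per-subject motion stored in
#'   `series$motion` is used automatically when the model was built without
#'   motion columns but the series carries them (in that case the design is
#'   rebuilt per subject).
#' @param zscore z-score each run after residualization. Default TRUE.
#' @return a [roi_ts()] object with stage "zscored" (or "residual").
#' @export
regress_out <- function(series, model, zscore = TRUE) {
  stopifnot(inherits(series, "roi_ts"), inherits(model, "nuisance_model"))
  if (series$stage != "raw") {
    stop("regress_out expects a raw series (stage is '", series$stage, "')")
  }
  d <- dim(series$data)
  S <- d[1]
  out <- series$data
  run_idx <- .run_index_list(series$run_lens)
  per_subject_motion <- !is.null(series$motion) &&
    !any(grepl("^motion", colnames(model$design[[1]])))
  for (s in seq_len(S)) {
    designs <- model$design
    if (per_subject_motion) {
      designs <- lapply(seq_along(designs), function(r) {
        M <- series$motion[[s]][run_idx[[r]], , drop = FALSE]
        colnames(M) <- paste0("motion", 1:6)
        D <- apply(M, 2, function(col) c(0, diff(col)))
        colnames(D) <- paste0("dmotion", 1:6)
        cbind(designs[[r]], M, D)
      })
    }
    for (r in seq_along(run_idx)) {
      X <- designs[[r]]
      qrX <- qr(X)
      if (qrX$rank < ncol(X)) {
        dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
        stop("rank-deficient design in run ", r, "; collinear columns: ",
             paste(dropped, collapse = ", "))
      }
      Y <- t(out[s, , run_idx[[r]], drop = TRUE])
      if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
      res <- qr.resid(qrX, Y)
      if (zscore) {
        res <- scale(res)
        res[is.na(res)] <- 0  # zero-variance residual stays flat
      }
      out[s, , run_idx[[r]]] <- t(res)
    }
  }
  roi_ts(out, series$rois, series$tr, series$run_lens,
         stage = if (zscore) "zscored" else "residual",
         motion = series$motion)
}

#' Label TRs as approach, retreat or excluded
#'
#' Assigns each TR of the experiment exactly one label. TRs are excluded,
#' with a recorded reason, when they fall in rest/blank periods (`rest`), in
#' the first `onset_skip_s` seconds of a block (`block_onset`), within
#' `shock_window_s` seconds after a shock (`post_shock`, closed-open window),
#' or when the circle distance fails the proximity gate
#' (`distance_cutoff`). Remaining TRs are labeled by the sign of the TR-to-TR
#' distance change: negative change (circles closing in) is `approach`,
#' positive change is `retreat`, and exact zero change is excluded as a
#' `tie`.
#'
#' The proximity gate retains, with `gate = "near"` (default), TRs whose
#' distance is at most `cutoff_fraction` times the maximum distance observed
#' over the whole experiment -- restricting analysis to periods when the
#' circles are in relatively close proximity. `gate = "far"` retains TRs with
#' distance at least that threshold instead.
#'
#' @param dist distance table as produced by [simulate_paradigm()]
#'   (columns run, block, tr_index, distance; in-block TRs only).
#' @param schedule an [build_schedule()] object.
#' @param shock_times list of numeric vectors (one per run, seconds within
#'   run), or a data frame with columns `run` and `onset`.
#' @param cutoff_fraction proximity-gate fraction in (0, 1]. Default 0.75.
#' @param onset_skip_s seconds discarded at each block onset. Default 15.
#' @param shock_window_s seconds discarded after each shock. Default 15.
#' @param gate gate direction, `"near"` or `"far"`. Default `"near"`.
#' @return an object of class `condition_labels`: tibble with columns `run`,
#'   `tr_index` (0-based within run), `label` (approach/retreat/excluded) and
#'   `reason` (rest, block_onset, post_shock, distance_cutoff, tie, or NA for
#'   labeled TRs), plus `distance`. Attributes carry the TR, volumes per run
#'   and the experiment-wide maximum distance.
#' @export
label_conditions <- function(dist, schedule, shock_times,
                             cutoff_fraction = 0.75, onset_skip_s = 15,
                             shock_window_s = 15,
                             gate = c("near", "far")) {
  gate <- match.arg(gate)
  stopifnot(inherits(schedule, "event_schedule"))
  if (!is.numeric(cutoff_fraction) || cutoff_fraction <= 0 ||
      cutoff_fraction > 1) {
    stop("parameter error: cutoff_fraction must be in (0, 1]")
  }
  if (is.data.frame(shock_times)) {
    shock_times <- lapply(seq_len(schedule$n_runs) - 1L, function(r) {
      shock_times$onset[shock_times$run == r]
    })
  }
  L <- schedule$vols_per_run
  tr <- schedule$tr
  onset_skip <- as.integer(round(onset_skip_s / tr))
  grid <- tibble::tibble(
    run = rep(seq_len(schedule$n_runs) - 1L, each = L),
    tr_index = rep(seq_len(L) - 1L, schedule$n_runs))
  grid$block <- rep(.block_of_tr(schedule, seq_len(L) - 1L),
                    schedule$n_runs)
  key <- paste(grid$run, grid$tr_index)
  dk <- paste(dist$run, dist$tr_index)
  grid$distance <- dist$distance[match(key, dk)]
  max_dist <- max(dist$distance, na.rm = TRUE)
  thr <- cutoff_fraction * max_dist

  # distance change from the previous TR of the same run and block
  delta <- rep(NA_real_, nrow(grid))
  same_prev <- c(FALSE, grid$run[-1] == grid$run[-nrow(grid)] &
                   !is.na(grid$block[-1]) & !is.na(grid$block[-nrow(grid)]) &
                   grid$block[-1] == grid$block[-nrow(grid)])
  delta[same_prev] <- grid$distance[same_prev] -
    grid$distance[which(same_prev) - 1L]

  t0 <- grid$tr_index * tr
  in_block <- !is.na(grid$block)
  onset_of_block <- schedule$block_onsets[grid$block]
  is_onset <- in_block & (t0 - onset_of_block) < onset_skip * tr
  post_shock <- rep(FALSE, nrow(grid))
  for (r in seq_len(schedule$n_runs) - 1L) {
    st <- shock_times[[r + 1L]]
    if (length(st) == 0) next
    sel <- grid$run == r
    tt <- t0[sel]
    hit <- vapply(tt, function(x) any(x >= st & x < st + shock_window_s),
                  logical(1))
    post_shock[sel] <- hit
  }
  gate_fail <- in_block &
    (if (gate == "near") grid$distance > thr else grid$distance < thr)
  gate_fail[is.na(gate_fail)] <- FALSE
  tie <- in_block & (is.na(delta) | delta == 0)

  reason <- rep(NA_character_, nrow(grid))
  reason[tie] <- "tie"
  reason[gate_fail] <- "distance_cutoff"
  reason[post_shock] <- "post_shock"
  reason[is_onset] <- "block_onset"
  reason[!in_block] <- "rest"
  label <- ifelse(!is.na(reason), "excluded",
                  ifelse(delta < 0, "approach", "retreat"))
  out <- tibble::tibble(run = grid$run, tr_index = grid$tr_index,
                        label = label, reason = reason,
                        distance = grid$distance)
  structure(out, class = c("condition_labels", class(out)),
            tr = tr, vols_per_run = L, max_distance = max_dist,
            cutoff_fraction = cutoff_fraction, gate = gate)
}
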