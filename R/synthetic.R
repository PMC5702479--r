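#' Network-pair coupling specification for the synthetic generator
#'
#' Describes, per unordered network pair, the baseline correlation of the
#' shared (stimulus-locked) innovations and the change of that correlation
#' per second of within-segment time for each condition. Pairs not listed
#' get `default_base` and zero slopes.
#'
#' @param pairs data frame with columns `n1`, `n2`, `base`,
#'   `approach_slope`, `retreat_slope` (slopes in correlation units per
#'   second), or NULL for a constant-coupling spec.
#' @param default_base baseline correlation for unlisted pairs. Default 0.
#' @return tibble of class `coupling_spec`.
#' @export
coupling_spec <- function(pairs = NULL, default_base = 0) {
  if (is.null(pairs)) {
    pairs <- data.frame(n1 = character(0), n2 = character(0),
                        base = numeric(0), approach_slope = numeric(0),
                        retreat_slope = numeric(0))
  }
  pairs <- tibble::as_tibble(pairs)
  need <- c("n1", "n2", "base", "approach_slope", "retreat_slope")
  for (col in setdiff(need, names(pairs))) pairs[[col]] <- 0
  out <- pairs[need]
  attr(out, "default_base") <- default_base
  class(out) <- c("coupling_spec", class(out))
  out
}

# lookup (base, slope) for an unordered network pair
.coupling_pair <- function(spec, a, b, condition) {
  hit <- (spec$n1 == a & spec$n2 == b) | (spec$n1 == b & spec$n2 == a)
  if (!any(hit)) {
    return(c(base = attr(spec, "default_base"), slope = 0))
  }
  row <- spec[which(hit)[1], ]
  slope <- switch(condition,
                  approach = row$approach_slope,
                  retreat = row$retreat_slope,
                  0)
  c(base = row$base, slope = slope)
}

# innovation correlation matrix at within-segment time tau (seconds)
.coupling_matrix <- function(partition, spec, condition, tau) {
  rois <- partition$roi
  nets <- partition$network
  R <- length(rois)
  un <- unique(nets)
  M <- diag(1, R)
  for (a in seq_along(un)) {
    for (b in a:length(un)) {
      p <- .coupling_pair(spec, un[a], un[b], condition)
      rho <- p["base"] + p["slope"] * tau
      ia <- which(nets == un[a]); ib <- which(nets == un[b])
      M[ia, ib] <- rho
      M[ib, ia] <- rho
    }
  }
  diag(M) <- 1
  dimnames(M) <- list(rois, rois)
  M
}

.check_psd <- function(partition, spec, condition, tau) {
  M <- .coupling_matrix(partition, spec, condition, tau)
  off <- M; diag(off) <- 0
  if (any(abs(off) > 1)) {
    bad <- which(abs(off) > 1, arr.ind = TRUE)[1, ]
    nets <- partition$network
    stop("configuration error: innovation correlation out of [-1, 1] at ",
         "within-segment time ", tau, " s (", condition, ") for network ",
         "pair ", nets[bad[1]], " - ", nets[bad[2]])
  }
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    off <- abs(M); diag(off) <- 0
    bad <- which(off == max(off), arr.ind = TRUE)[1, ]
    nets <- partition$network
    stop("configuration error: innovation correlation matrix not positive ",
         "semi-definite at within-segment time ", tau, " s (", condition,
         "); min eigenvalue ", signif(min(ev), 3),
         ", strongest coupling at network pair ",
         nets[bad[1]], " - ", nets[bad[2]])
  }
  invisible(M)
}

#' Configuration of the synthetic multi-subject BOLD generator
#'
#' The generator produces, for each subject, ROI time series of the form
#' shared stimulus-locked signal + subject noise + polynomial drift + motion
#' artifact. The shared signal is drawn per TR from a multivariate normal
#' whose cross-ROI correlation follows the coupling spec: inside an
#' approach (retreat) segment the pairwise correlation of the innovations
#' ramps as `base + approach_slope * tau` (`retreat_slope`), with `tau` the
#' within-segment time in seconds. The ramp acts on the innovation
#' correlations only -- per-ROI variance stays constant -- so downstream ISC
#' changes reflect coupling, not amplitude. Implied correlation matrices are
#' checked for positive semi-definiteness up front (at `tau = 0` and
#' `psd_check_s`; since the matrix is linear in `tau` and the PSD cone is
#' convex, endpoint checks cover the interval) and invalid configurations
#' fail loudly.
#'
#' @param partition partition tibble, see [read_partition()]; its ROI set
#'   defines the generated ROIs.
#' @param n_subjects number of subjects, >= 3.
#' @param shared_variance variance of the shared stimulus-locked component.
#' @param coupling a [coupling_spec()].
#' @param noise_sd SD of subject-specific noise. Default 1.
#' @param ar1_phi AR(1) coefficient of the subject noise (0 = white).
#' @param drift_amp scale of per-run polynomial drift terms. Default 0.5.
#' @param motion_amp scale of motion-artifact loadings. Default 0.5.
#' @param block_amp amplitude of the HRF-convolved block-evoked response
#'   added identically to every ROI and subject. Default 1.
#' @param hrf_convolve convolve the shared component with the HRF. Default
#'   FALSE (convolution smears the per-TR coupling ramp the ground truth is
#'   defined on; the block-evoked component is HRF-shaped regardless).
#' @param psd_check_s largest within-segment time checked for positive
#'   semi-definiteness at construction. Default 12.
#' @param seed default seed used by [generate_dataset()].
#' @return object of class `generator_config`.
#' @export
generator_config <- function(partition, n_subjects, shared_variance = 1,
                             coupling = coupling_spec(), noise_sd = 1,
                             ar1_phi = 0, drift_amp = 0.5, motion_amp = 0.5,
                             block_amp = 1, hrf_convolve = FALSE,
                             psd_check_s = 12, seed = 1) {
  stopifnot(n_subjects >= 3, shared_variance >= 0, noise_sd >= 0,
            ar1_phi >= 0, ar1_phi < 1)
  stopifnot(inherits(coupling, "coupling_spec"))
  for (cond in c("approach", "retreat")) {
    .check_psd(partition, coupling, cond, 0)
    .check_psd(partition, coupling, cond, psd_check_s)
  }
  structure(list(partition = partition, n_subjects = n_subjects,
                 shared_variance = shared_variance, coupling = coupling,
                 noise_sd = noise_sd, ar1_phi = ar1_phi,
                 drift_amp = drift_amp, motion_amp = motion_amp,
                 block_amp = block_amp, hrf_convolve = hrf_convolve,
                 psd_check_s = psd_check_s, seed = seed),
            class = "generator_config")
}

#' Analytic expected intersubject correlations under the generator
#'
#' For shared variance `v`, noise variance `s2` and `N` subjects, the
#' expected leave-one-out ISC between ROI i of one subject and the average
#' of the others' ROI j is `v * rho_ij / (sqrt(v + s2) * sqrt(v + s2 /
#' (N - 1)))`, with `rho_ij` the innovation correlation (1 on the diagonal).
#' The prediction applies to the residualized series (drift, motion and the
#' block-evoked component removed).
#'
#' @param config a [generator_config()].
#' @param condition `"approach"`, `"retreat"` or `"none"` (baseline).
#' @param tau within-segment time in seconds. Default 0.
#' @return matrix of expected ISM entries (ROIs x ROIs).
#' @export
expected_isc <- function(config, condition = "none", tau = 0) {
  stopifnot(inherits(config, "generator_config"))
  v <- config$shared_variance
  s2 <- config$noise_sd^2
  N <- config$n_subjects
  denom <- sqrt(v + s2) * sqrt(v + s2 / (N - 1))
  rho <- .coupling_matrix(config$partition, config$coupling, condition, tau)
  if (denom == 0) return(rho * NA_real_)
  v * rho / denom
}

#' Construct deterministic condition labels with prescribed segments
#'
#' Lays out approach and retreat segments of the requested lengths into the
#' usable portion of each block (after the onset skip), alternating
#' conditions and separating consecutive segments by one excluded TR. Useful
#' for building datasets with a known segment geometry without simulating
#' circle motion.
#'
#' @param schedule an [build_schedule()] object.
#' @param seg_lens_approach,seg_lens_retreat integer vectors of segment
#'   lengths (TRs).
#' @param onset_skip_s seconds skipped at each block onset. Default 15.
#' @return a `condition_labels` tibble (distance is NA throughout).
#' @export
synthetic_labels <- function(schedule, seg_lens_approach, seg_lens_retreat,
                             onset_skip_s = 15) {
  stopifnot(inherits(schedule, "event_schedule"))
  L <- schedule$vols_per_run
  tr <- schedule$tr
  skip <- as.integer(round(onset_skip_s / tr))
  grid <- tibble::tibble(
    run = rep(seq_len(schedule$n_runs) - 1L, each = L),
    tr_index = rep(seq_len(L) - 1L, schedule$n_runs))
  blk <- rep(.block_of_tr(schedule, seq_len(L) - 1L), schedule$n_runs)
  label <- rep("excluded", nrow(grid))
  reason <- rep("rest", nrow(grid))
  t0 <- grid$tr_index * tr
  in_block <- !is.na(blk)
  onset_of_block <- schedule$block_onsets[blk]
  is_onset <- in_block & (t0 - onset_of_block) < skip * tr
  reason[in_block] <- "tie"
  reason[is_onset] <- "block_onset"
  usable <- in_block & !is_onset

  qa <- as.integer(seg_lens_approach)
  qr_ <- as.integer(seg_lens_retreat)
  turn <- "approach"
  spans <- split(which(usable),
                 cumsum(c(1L, diff(which(usable)) != 1L)))
  for (span in spans) {
    pos <- 1L
    while (pos <= length(span)) {
      if ((turn == "approach" && !length(qa)) ||
          (turn == "retreat" && !length(qr_))) {
        other <- if (turn == "approach") qr_ else qa
        if (!length(other)) break
        turn <- if (turn == "approach") "retreat" else "approach"
        next
      }
      len <- if (turn == "approach") qa[1] else qr_[1]
      if (pos + len - 1L > length(span)) break
      idx <- span[pos:(pos + len - 1L)]
      label[idx] <- turn
      reason[idx] <- NA_character_
      if (turn == "approach") qa <- qa[-1] else qr_ <- qr_[-1]
      turn <- if (turn == "approach") "retreat" else "approach"
      pos <- pos + len + 1L   # one excluded separator TR
    }
    if (!length(qa) && !length(qr_)) break
  }
  if (length(qa) || length(qr_)) {
    stop("schedule too short for the requested segments (",
         length(qa), " approach and ", length(qr_), " retreat left over)")
  }
  out <- tibble::tibble(run = grid$run, tr_index = grid$tr_index,
                        label = label, reason = reason,
                        distance = NA_real_)
  structure(out, class = c("condition_labels", class(out)),
            tr = tr, vols_per_run = L, max_distance = NA_real_,
            cutoff_fraction = NA_real_, gate = NA_character_)
}

#' Generate a synthetic multi-subject ROI dataset with known ground truth
#'
#' Draws the dataset described by a [generator_config()] on the TR grid of
#' `schedule`, with cross-ROI coupling of the shared innovations following
#' the condition labels: inside an approach/retreat segment the innovation
#' correlation ramps with within-segment time per the coupling spec; outside
#' segments the baseline coupling applies.
#'
#' @param config a [generator_config()].
#' @param schedule an [build_schedule()] object.
#' @param labels a `condition_labels` object aligned to the schedule.
#' @param seed integer seed; the dataset is bit-reproducible given it.
#' @return list with `series` (raw [roi_ts()], per-subject motion tables
#'   attached), `truth` (expected diagonal ISC, per-pair true coupling
#'   slopes in innovation-correlation and ISC units), and `config`.
#' @export
generate_dataset <- function(config, schedule, labels,
                             seed = config$seed) {
  stopifnot(inherits(config, "generator_config"),
            inherits(schedule, "event_schedule"))
  labels <- labels[order(labels$run, labels$tr_index), ]
  L <- schedule$vols_per_run
  n_runs <- schedule$n_runs
  T_all <- L * n_runs
  if (nrow(labels) != T_all) {
    stop("alignment error: labels do not cover the schedule (",
         nrow(labels), " rows for ", T_all, " TRs)")
  }
  part <- config$partition
  rois <- part$roi
  R <- length(rois)
  S <- config$n_subjects
  tr <- schedule$tr

  # per-TR condition and within-segment time
  segs <- extract_segments(labels)
  cond <- rep("none", T_all)
  tau <- rep(0, T_all)
  for (k in seq_len(nrow(segs))) {
    idx <- segs$start_global[k] + seq_len(segs$length[k])
    cond[idx] <- segs$condition[k]
    tau[idx] <- (seq_len(segs$length[k]) - 1) * tr
  }
  for (cn in c("approach", "retreat")) {
    if (any(cond == cn)) {
      .check_psd(part, config$coupling, cn, max(tau[cond == cn]))
    }
  }

  set.seed(seed)
  v <- config$shared_variance
  key <- paste(cond, tau)
  E <- matrix(stats::rnorm(R * T_all), R, T_all)
  shared <- matrix(0, R, T_all)
  for (k in unique(key)) {
    idx <- which(key == k)
    Sig <- .coupling_matrix(part, config$coupling, cond[idx[1]],
                            tau[idx[1]])
    Lc <- chol(Sig + diag(1e-10, R))
    shared[, idx] <- t(Lc) %*% E[, idx, drop = FALSE]
  }
  shared <- shared * sqrt(v)
  run_idx <- .run_index_list(rep(L, n_runs))
  if (config$hrf_convolve) {
    kern <- hrf_kernel(tr)
    for (ri in run_idx) {
      for (i in seq_len(R)) {
        x <- shared[i, ri]
        y <- .convolve_causal(x, kern)
        s0 <- stats::sd(x); s1 <- stats::sd(y)
        shared[i, ri] <- if (s1 > 0) y * s0 / s1 else y
      }
    }
  }
  boxcar <- as.numeric(!is.na(.block_of_tr(schedule, seq_len(L) - 1L)))
  block_reg <- .convolve_causal(boxcar, hrf_kernel(tr))
  block_reg <- block_reg / max(abs(block_reg))
  evoked <- config$block_amp * rep(block_reg, n_runs)

  data <- array(NA_real_, c(S, R, T_all))
  motion <- vector("list", S)
  for (s in seq_len(S)) {
    eps <- matrix(stats::rnorm(R * T_all, sd = config$noise_sd), R, T_all)
    if (config$ar1_phi > 0) {
      for (ri in run_idx) {
        for (i in seq_len(R)) {
          eps[i, ri] <- as.numeric(stats::filter(
            eps[i, ri] * sqrt(1 - config$ar1_phi^2),
            config$ar1_phi, method = "recursive"))
        }
      }
    }
    drift <- matrix(0, R, T_all)
    art <- matrix(0, R, T_all)
    msub <- matrix(0, T_all, 6)
    for (ri in run_idx) {
      Lr <- length(ri)
      P <- stats::poly(seq_len(Lr), degree = 4) * sqrt(Lr)
      coef <- matrix(stats::rnorm(4 * R, sd = config$drift_amp), 4, R)
      drift[, ri] <- t(P %*% coef)
      M <- apply(matrix(stats::rnorm(Lr * 6, sd = 0.02), Lr, 6), 2, cumsum)
      msub[ri, ] <- M
      B <- matrix(stats::rnorm(6 * R, sd = config$motion_amp), 6, R)
      art[, ri] <- t(M %*% B)
    }
    data[s, , ] <- shared + matrix(evoked, R, T_all, byrow = TRUE) +
      eps + drift + art
    motion[[s]] <- msub
  }
  # with no motion artifact there is nothing to regress out per subject
  if (config$motion_amp == 0) motion <- NULL
  series <- roi_ts(data, rois, tr, rep(L, n_runs), stage = "raw",
                   motion = motion)

  s2 <- config$noise_sd^2
  denom <- sqrt(v + s2) * sqrt(v + s2 / (S - 1))
  isc_scale <- if (denom > 0) v / denom else NA_real_
  spec <- config$coupling
  truth_slopes <- tibble::tibble(
    n1 = rep(spec$n1, 2), n2 = rep(spec$n2, 2),
    condition = rep(c("approach", "retreat"), each = nrow(spec)),
    coupling_slope = c(spec$approach_slope, spec$retreat_slope))
  truth_slopes$isc_slope <- truth_slopes$coupling_slope * isc_scale
  truth <- list(expected_diag_isc = isc_scale,
                isc_scale = isc_scale,
                slopes = truth_slopes,
                shared_variance = v, noise_sd = config$noise_sd,
                n_subjects = S)
  list(series = series, truth = truth, config = config)
}
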