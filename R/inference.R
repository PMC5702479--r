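#' Ordinary least-squares slope of a weight trajectory
#'
#' @param t numeric time values (seconds).
#' @param w weight values, same length as `t` (>= 2 points).
#' @return slope scalar (weight units per second).
#' @export
fit_slope <- function(t, w) {
  stopifnot(length(t) == length(w), length(t) >= 2)
  tm <- t - mean(t)
  sum(tm * (w - mean(w))) / sum(tm^2)
}

#' Slopes for every trajectory in a weight table
#'
#' @param traj long-format trajectory tibble from [weight_trajectories()].
#' @return tibble with one row per (`n1`, `n2`, `condition`, `mode`):
#'   `slope` and `n_t` (time points used).
#' @export
fit_slopes <- function(traj) {
  traj |>
    dplyr::group_by(.data$n1, .data$n2, .data$condition, .data$mode) |>
    dplyr::summarise(slope = fit_slope(.data$t, .data$weight),
                     n_t = dplyr::n(), .groups = "drop")
}

# uniform circular shift amounts, one per subject x run; shifts in 1..L-1
.draw_shifts <- function(S, run_lens) {
  vapply(run_lens, function(L) sample.int(L - 1L, S, replace = TRUE),
         integer(S))
}

# gather indices realizing a circular shift of each run span
.shift_index <- function(run_lens, shifts) {
  starts <- cumsum(c(0L, utils::head(run_lens, -1)))
  idx <- integer(sum(run_lens))
  for (r in seq_along(run_lens)) {
    L <- run_lens[r]
    k <- seq_len(L) - 1L
    idx[starts[r] + seq_len(L)] <- starts[r] + ((k + shifts[r]) %% L) + 1L
  }
  idx
}

# precompute per-pair index sets for the fast weight path
.pair_index <- function(partition, rois, pairs) {
  lapply(seq_len(nrow(pairs)), function(k) {
    list(i1 = .partition_index(partition, pairs$n1[k], rois),
         i2 = .partition_index(partition, pairs$n2[k], rois),
         same = identical(pairs$n1[k], pairs$n2[k]))
  })
}

#' Circular-shift permutation null for weights and slopes
#'
#' Each realization independently applies, per subject and per run, a
#' uniform circular shift (1 to run length - 1 TRs) to the z-scored residual
#' series, breaking temporal alignment across participants while preserving
#' each series' autocorrelation. The dynamic-ISC -> network-weight -> slope
#' pipeline is then re-run on the shifted data using the ORIGINAL slice
#' indices (the paradigm timing and sampling scheme are not part of the
#' null). Null distributions are collected for every weight at every slice
#' time, for approach and retreat slopes, and for the approach - retreat
#' slope difference.
#'
#' @param series z-scored [roi_ts()] object.
#' @param seg [build_slices()] segment index (from the unshifted labels).
#' @param partition partition tibble.
#' @param pairs 2-column data frame of network pairs to evaluate; default
#'   all unordered pairs.
#' @param modes weight modes to evaluate. Default `"positive"`.
#' @param n_realizations number of realizations (>= 100; a warning is
#'   emitted below 1000). Default 10000.
#' @param include_diagonal see [network_weight()].
#' @param seed integer seed; the null is reproducible given it.
#' @return object of class `isc_null`: list with `weights` (keys tibble +
#'   realizations x keys matrix), `slopes`, `slope_diff` (same layout),
#'   `n_realizations`, `seed`.
#' @export
circular_null <- function(series, seg, partition, pairs = NULL,
                          modes = "positive", n_realizations = 10000,
                          include_diagonal = TRUE, seed = 1) {
  stopifnot(inherits(series, "roi_ts"), inherits(seg, "segment_index"))
  if (n_realizations < 100) {
    stop("parameter error: n_realizations must be at least 100")
  }
  if (n_realizations < 1000) {
    warning("fewer than 1000 realizations; null tails will be coarse")
  }
  if (any(series$run_lens < 2)) {
    stop("run too short to shift meaningfully (< 2 TRs)")
  }
  if (is.null(pairs)) {
    nets <- unique(partition$network)
    eg <- expand.grid(a = seq_along(nets), b = seq_along(nets))
    eg <- eg[eg$a <= eg$b, ]
    pairs <- data.frame(n1 = nets[eg$a], n2 = nets[eg$b],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- as.data.frame(pairs)
    names(pairs) <- c("n1", "n2")
  }
  modes <- match.arg(modes, c("positive", "negative", "all"),
                     several.ok = TRUE)
  S <- dim(series$data)[1]
  rois <- series$rois
  pidx <- .pair_index(partition, rois, pairs)

  slice_tbl <- list()
  for (cond in names(seg$slices)) {
    for (tname in names(seg$slices[[cond]])) {
      slice_tbl[[length(slice_tbl) + 1]] <- list(
        condition = cond, t = as.numeric(tname),
        idx = seg$slices[[cond]][[tname]])
    }
  }
  if (!length(slice_tbl)) stop("no usable slices in the segment index")

  wkeys <- dplyr::bind_rows(lapply(slice_tbl, function(sl) {
    tibble::tibble(n1 = pairs$n1, n2 = pairs$n2, condition = sl$condition,
                   t = sl$t)
  }))
  wkeys <- tidyr_expand_modes(wkeys, modes)
  key_id <- paste(wkeys$n1, wkeys$n2, wkeys$condition, wkeys$t, wkeys$mode)

  Ylist <- lapply(seq_len(S), function(s) {
    M <- series$data[s, , , drop = FALSE]
    dim(M) <- dim(M)[2:3]
    M
  })

  set.seed(seed)
  W <- matrix(NA_real_, n_realizations, nrow(wkeys))
  colnames(W) <- key_id
  n_pairs <- nrow(pairs)
  n_modes <- length(modes)
  for (r in seq_len(n_realizations)) {
    shifts <- .draw_shifts(S, series$run_lens)  # S x runs
    perms <- lapply(seq_len(S), function(s) {
      .shift_index(series$run_lens, shifts[s, ])
    })
    col <- 0L
    for (sl in slice_tbl) {
      Ymats <- lapply(seq_len(S), function(s) {
        Ylist[[s]][, perms[[s]][sl$idx], drop = FALSE]
      })
      G <- .ism_group_core(Ymats)$matrix
      for (k in seq_len(n_pairs)) {
        for (mode in modes) {
          col <- col + 1L
          W[r, col] <- .weight_core(G, pidx[[k]]$i1, pidx[[k]]$i2, mode,
                                    include_diagonal, pidx[[k]]$same)
        }
      }
    }
  }

  skeys <- unique(wkeys[c("n1", "n2", "condition", "mode")])
  Smat <- matrix(NA_real_, n_realizations, nrow(skeys))
  for (k in seq_len(nrow(skeys))) {
    sel <- wkeys$n1 == skeys$n1[k] & wkeys$n2 == skeys$n2[k] &
      wkeys$condition == skeys$condition[k] & wkeys$mode == skeys$mode[k]
    tt <- wkeys$t[sel]
    if (sum(sel) >= 2) {
      tm <- tt - mean(tt)
      Smat[, k] <- (W[, sel, drop = FALSE] %*% tm -
                      rowSums(W[, sel, drop = FALSE]) * mean(tm)) /
        sum(tm^2)
    }
  }
  dkeys <- unique(skeys[c("n1", "n2", "mode")])
  Dmat <- matrix(NA_real_, n_realizations, nrow(dkeys))
  for (k in seq_len(nrow(dkeys))) {
    ia <- which(skeys$n1 == dkeys$n1[k] & skeys$n2 == dkeys$n2[k] &
                  skeys$mode == dkeys$mode[k] &
                  skeys$condition == "approach")
    ir <- which(skeys$n1 == dkeys$n1[k] & skeys$n2 == dkeys$n2[k] &
                  skeys$mode == dkeys$mode[k] &
                  skeys$condition == "retreat")
    if (length(ia) == 1 && length(ir) == 1) {
      Dmat[, k] <- Smat[, ia] - Smat[, ir]
    }
  }
  structure(list(weights = list(keys = wkeys, values = W),
                 slopes = list(keys = skeys, values = Smat),
                 slope_diff = list(keys = dkeys, values = Dmat),
                 n_realizations = n_realizations, seed = seed),
            class = "isc_null")
}

# replicate weight keys over modes (small helper, avoids a tidyr dependency)
tidyr_expand_modes <- function(keys, modes) {
  out <- keys[rep(seq_len(nrow(keys)), each = length(modes)), ]
  out$mode <- rep(modes, nrow(keys))
  out
}

# two-sided permutation p-value with add-one smoothing
.perm_p <- function(obs, null) {
  null <- null[is.finite(null)]
  n <- length(null)
  ge <- sum(null >= obs)
  le <- sum(null <= obs)
  min(1, 2 * (min(ge, le) + 1) / (n + 1))
}

#' Test observed slopes against circular-shift nulls
#'
#' Computes two-sided permutation p-values (add-one smoothing) for the
#' approach and retreat slopes of every trajectory and for their
#' difference, and emits null-mean-corrected weights (observed weight minus
#' the null mean at the matching condition, time and mode -- the means
#' expected by chance are generally nonzero because slice sample counts are
#' unequal).
#'
#' @param traj observed weight trajectories from [weight_trajectories()].
#' @param null an `isc_null` from [circular_null()] computed on the same
#'   series/slices.
#' @return object of class `slope_result`: list with `slopes` (tibble:
#'   n1, n2, condition, mode, slope, p_value), `slope_diff` (tibble: n1, n2,
#'   mode, diff, p_value), and `weights` (traj with `null_mean` and
#'   `corrected_weight` columns). No correction for multiple comparisons
#'   across network pairs is applied; p-values are raw.
#' @export
test_slopes <- function(traj, null) {
  stopifnot(inherits(null, "isc_null"))
  obs <- fit_slopes(traj)
  sk <- null$slopes$keys
  obs$p_value <- NA_real_
  for (k in seq_len(nrow(obs))) {
    j <- which(sk$n1 == obs$n1[k] & sk$n2 == obs$n2[k] &
                 sk$condition == obs$condition[k] & sk$mode == obs$mode[k])
    if (length(j) == 1 && any(is.finite(null$slopes$values[, j]))) {
      obs$p_value[k] <- .perm_p(obs$slope[k], null$slopes$values[, j])
    }
  }
  wide <- obs
  dk <- null$slope_diff$keys
  diffs <- list()
  for (k in seq_len(nrow(dk))) {
    a <- wide$slope[wide$n1 == dk$n1[k] & wide$n2 == dk$n2[k] &
                      wide$mode == dk$mode[k] &
                      wide$condition == "approach"]
    r <- wide$slope[wide$n1 == dk$n1[k] & wide$n2 == dk$n2[k] &
                      wide$mode == dk$mode[k] &
                      wide$condition == "retreat"]
    if (length(a) == 1 && length(r) == 1 &&
        any(is.finite(null$slope_diff$values[, k]))) {
      diffs[[length(diffs) + 1]] <- tibble::tibble(
        n1 = dk$n1[k], n2 = dk$n2[k], mode = dk$mode[k], diff = a - r,
        p_value = .perm_p(a - r, null$slope_diff$values[, k]))
    }
  }
  wk <- null$weights$keys
  null_means <- colMeans(null$weights$values)
  traj$null_mean <- NA_real_
  for (k in seq_len(nrow(traj))) {
    j <- which(wk$n1 == traj$n1[k] & wk$n2 == traj$n2[k] &
                 wk$condition == traj$condition[k] & wk$t == traj$t[k] &
                 wk$mode == traj$mode[k])
    if (length(j) == 1) traj$null_mean[k] <- null_means[j]
  }
  traj$corrected_weight <- traj$weight - traj$null_mean
  structure(list(slopes = obs, slope_diff = dplyr::bind_rows(diffs),
                 weights = traj),
            class = "slope_result")
}

#' Jackknife standard error from leave-one-out estimates
#'
#' @param loo numeric vector of leave-one-out estimates.
#' @return `sqrt((n - 1) / n * sum((loo - mean(loo))^2))`.
#' @export
jackknife_se <- function(loo) {
  n <- length(loo)
  stopifnot(n >= 2)
  sqrt((n - 1) / n * sum((loo - mean(loo))^2))
}

#' Leave-one-subject-out confidence band for a weight trajectory
#'
#' Recomputes the group weight at every slice with each subject left out in
#' turn; the band is the full-sample estimate plus/minus the normal quantile
#' of `level` times the jackknife SE.
#'
#' @param series z-scored [roi_ts()] object with >= 5 subjects.
#' @param seg [build_slices()] segment index.
#' @param partition partition tibble.
#' @param n1,n2 network pair.
#' @param mode weight mode. Default "positive".
#' @param include_diagonal see [network_weight()].
#' @param level band coverage. Default 0.90.
#' @return tibble with columns `condition`, `t`, `estimate`, `se`, `lower`,
#'   `upper`.
#' @export
confidence_band <- function(series, seg, partition, n1, n2,
                            mode = "positive", include_diagonal = TRUE,
                            level = 0.90) {
  stopifnot(inherits(series, "roi_ts"), inherits(seg, "segment_index"))
  S <- dim(series$data)[1]
  if (S < 5) stop("need at least 5 subjects for a jackknife band")
  z <- stats::qnorm(1 - (1 - level) / 2)
  i1 <- .partition_index(partition, n1, series$rois)
  i2 <- .partition_index(partition, n2, series$rois)
  same <- identical(n1, n2)
  rows <- list()
  for (cond in names(seg$slices)) {
    for (tname in names(seg$slices[[cond]])) {
      idx <- seg$slices[[cond]][[tname]]
      Ymats <- .subject_mats(series, idx)
      full <- .weight_core(.ism_group_core(Ymats)$matrix, i1, i2, mode,
                           include_diagonal, same)
      loo <- vapply(seq_len(S), function(s) {
        .weight_core(.ism_group_core(Ymats[-s])$matrix, i1, i2, mode,
                     include_diagonal, same)
      }, numeric(1))
      se <- jackknife_se(loo)
      rows[[length(rows) + 1]] <- tibble::tibble(
        condition = cond, t = as.numeric(tname), estimate = full,
        se = se, lower = full - z * se, upper = full + z * se)
    }
  }
  dplyr::bind_rows(rows)
}
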