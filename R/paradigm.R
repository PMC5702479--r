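#' Build the block/run schedule of the moving-circles paradigm
#'
#' Each run consists of `n_blocks` blocks of circle motion lasting `block_s`
#' seconds, each preceded by `rest_s` seconds of blank screen, and the run
#' ends with `end_blank_s` seconds of blank screen. Functional volumes are
#' acquired every `tr` seconds, so a run spans
#' `(n_blocks * (rest_s + block_s) + end_blank_s) / tr` volumes.
#'
#' @param n_runs number of runs. Default 6.
#' @param n_blocks blocks per run. Default 6.
#' @param rest_s blank-screen rest before each block (seconds). Default 15.
#' @param block_s duration of circle motion per block (seconds). Default 60.
#' @param end_blank_s blank screen at the end of each run (seconds). Default 7.
#' @param tr repetition time (seconds). Default 1.0. All durations must be
#'   positive multiples of `tr`.
#' @return an object of class `event_schedule`: a list with the input
#'   parameters, per-run block onsets/offsets (seconds, relative to run
#'   start), `vols_per_run` and `total_vols`.
#' @examples
#' sched <- build_schedule()
#' sched$vols_per_run  # 457 with the default parameters
#' @export
build_schedule <- function(n_runs = 6, n_blocks = 6, rest_s = 15,
                           block_s = 60, end_blank_s = 7, tr = 1.0) {
  stopifnot(n_runs >= 1, n_blocks >= 1, tr > 0)
  durs <- c(rest_s = rest_s, block_s = block_s, end_blank_s = end_blank_s)
  if (any(durs < 0) || block_s <= 0) {
    stop("schedule error: durations must be positive")
  }
  mult <- durs / tr
  if (any(abs(mult - round(mult)) > 1e-9)) {
    bad <- names(durs)[abs(mult - round(mult)) > 1e-9]
    stop("schedule error: durations not multiples of TR: ",
         paste(bad, collapse = ", "))
  }
  onsets <- rest_s + (seq_len(n_blocks) - 1) * (rest_s + block_s)
  offsets <- onsets + block_s
  run_dur <- n_blocks * (rest_s + block_s) + end_blank_s
  structure(
    list(n_runs = n_runs, n_blocks = n_blocks, rest_s = rest_s,
         block_s = block_s, end_blank_s = end_blank_s, tr = tr,
         block_onsets = onsets, block_offsets = offsets,
         run_duration_s = run_dur,
         vols_per_run = as.integer(round(run_dur / tr)),
         total_vols = as.integer(round(run_dur / tr) * n_runs)),
    class = "event_schedule")
}

#' @export
print.event_schedule <- function(x, ...) {
  cat("<event_schedule> ", x$n_runs, " runs x ", x$n_blocks, " blocks (",
      x$rest_s, " s rest + ", x$block_s, " s motion), ", x$end_blank_s,
      " s end blank, TR = ", x$tr, " s -> ", x$vols_per_run,
      " volumes/run\n", sep = "")
  invisible(x)
}

# block id (1-based) for each 0-based TR index of a run, NA during rest/blank
.block_of_tr <- function(schedule, tr_index) {
  t0 <- tr_index * schedule$tr
  blk <- rep(NA_integer_, length(t0))
  for (b in seq_len(schedule$n_blocks)) {
    inside <- t0 >= schedule$block_onsets[b] & t0 < schedule$block_offsets[b]
    blk[inside] <- b
  }
  blk
}

#' Simulate momentum-smoothed random circle motion
#'
#' Each circle's per-coordinate displacement follows the AR(1) update
#' `d_t = (1 - c) * d_{t-1} + c * N(0, 1) * noise_scale`, evaluated every
#' `dt` seconds independently per coordinate and per circle; positions are
#' the running sum of displacements. The momentum term `(1 - c)` keeps the
#' motion smooth while the Gaussian innovations keep it unpredictable. With
#' `bounds` given, boundaries are reflective: the position is clamped to the
#' bounds and the offending displacement component is sign-flipped.
#'
#' At stationarity the per-coordinate displacement has standard deviation
#' `c * noise_scale / sqrt(1 - (1 - c)^2)` and lag-1 autocorrelation `1 - c`.
#'
#' @param duration simulated time (seconds); must be >= `dt`.
#' @param dt update interval (seconds). Default 0.05.
#' @param momentum_c momentum parameter `c` in (0, 1]. Default 0.2.
#' @param noise_scale standard deviation multiplier of the Gaussian
#'   innovation, in screen units. Default 0.015 (screen = unit square).
#' @param bounds screen rectangle `c(xmin, ymin, xmax, ymax)`, or `NULL` for
#'   unbounded motion. Default the unit square.
#' @param start 2 x n_circles matrix of starting positions (rows x, y);
#'   default places two circles at (0.25, 0.5) and (0.75, 0.5) scaled to the
#'   bounds, or those coordinates directly when unbounded.
#' @param n_circles number of circles. Default 2.
#' @param attract optional steering coefficient: a displacement of this
#'   magnitude (screen units per step) directed toward the other circle is
#'   added each step (two-circle case only). Default 0 (pure random motion).
#' @param seed integer seed; the trajectory is bit-reproducible given it.
#' @return an object of class `circle_trajectory`: list with `positions`
#'   (list of n_steps x 2 matrices, one per circle), `displacements` (same
#'   shape), `dt`, `momentum_c`, `bounds`, `steered`.
#' @examples
#' traj <- simulate_motion(10, seed = 1)
#' @export
simulate_motion <- function(duration, dt = 0.05, momentum_c = 0.2,
                            noise_scale = 0.015,
                            bounds = c(0, 0, 1, 1), start = NULL,
                            n_circles = 2, attract = 0, seed = NULL) {
  if (!is.finite(duration) || !is.finite(dt) || !is.finite(momentum_c) ||
      !is.finite(noise_scale)) {
    stop("parameter error: non-finite simulation parameter")
  }
  if (momentum_c <= 0 || momentum_c > 1) {
    stop("parameter error: momentum_c must be in (0, 1]")
  }
  if (dt <= 0) stop("parameter error: dt must be positive")
  if (duration < dt) stop("empty-trajectory error: duration < dt")
  if (!is.null(bounds)) {
    stopifnot(length(bounds) == 4)
    if (bounds[3] <= bounds[1] || bounds[4] <= bounds[2]) {
      stop("parameter error: degenerate bounds")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  n_steps <- as.integer(round(duration / dt))
  if (is.null(start)) {
    base <- cbind(c(0.25, 0.5), c(0.75, 0.5), c(0.5, 0.25), c(0.5, 0.75))
    start <- base[, seq_len(n_circles), drop = FALSE]
    if (!is.null(bounds)) {
      start[1, ] <- bounds[1] + start[1, ] * (bounds[3] - bounds[1])
      start[2, ] <- bounds[2] + start[2, ] * (bounds[4] - bounds[2])
    }
  }
  pos <- lapply(seq_len(n_circles), function(i) {
    m <- matrix(NA_real_, n_steps, 2, dimnames = list(NULL, c("x", "y")))
    m
  })
  disp <- lapply(seq_len(n_circles), function(i) matrix(0, n_steps, 2))
  x <- start          # 2 x n_circles current positions
  d <- matrix(0, 2, n_circles)  # current displacements
  cc <- momentum_c
  for (k in seq_len(n_steps)) {
    eps <- matrix(stats::rnorm(2 * n_circles), 2, n_circles)
    d <- (1 - cc) * d + cc * eps * noise_scale
    if (attract != 0 && n_circles == 2) {
      gap <- x[, 2] - x[, 1]
      len <- sqrt(sum(gap^2))
      if (len > 0) {
        pull <- attract * gap / len
        d[, 1] <- d[, 1] + pull
        d[, 2] <- d[, 2] - pull
      }
    }
    x <- x + d
    if (!is.null(bounds)) {
      for (i in seq_len(n_circles)) {
        for (j in 1:2) {
          lo <- bounds[j]; hi <- bounds[j + 2]
          if (x[j, i] < lo) { x[j, i] <- lo; d[j, i] <- -d[j, i] }
          if (x[j, i] > hi) { x[j, i] <- hi; d[j, i] <- -d[j, i] }
        }
      }
    }
    for (i in seq_len(n_circles)) {
      pos[[i]][k, ] <- x[, i]
      disp[[i]][k, ] <- d[, i]
    }
  }
  structure(
    list(positions = pos, displacements = disp, dt = dt,
         momentum_c = momentum_c, bounds = bounds,
         steered = attract != 0, n_steps = n_steps),
    class = "circle_trajectory")
}

# Euclidean distance between circles 1 and 2 at every sample
.traj_distance <- function(traj) {
  p1 <- traj$positions[[1]]
  p2 <- traj$positions[[2]]
  sqrt(rowSums((p1 - p2)^2))
}

#' Detect collision (shock) events in a trajectory
#'
#' The circles are in contact whenever the distance between their centers is
#' at most `2 * radius`. Consecutive contact samples are collapsed into a
#' single event at the time of first contact (0-based sample index times
#' `dt`, relative to the trajectory start).
#'
#' @param traj a [simulate_motion()] trajectory with two circles.
#' @param radius circle radius (screen units), > 0.
#' @return numeric vector of event times in seconds (possibly empty).
#' @export
detect_collisions <- function(traj, radius) {
  stopifnot(inherits(traj, "circle_trajectory"), length(traj$positions) >= 2)
  if (!is.finite(radius) || radius <= 0) {
    stop("parameter error: radius must be positive")
  }
  contact <- .traj_distance(traj) <= 2 * radius
  if (!any(contact)) return(numeric(0))
  onsets <- which(contact & !c(FALSE, contact[-length(contact)]))
  (onsets - 1) * traj$dt
}

#' Per-TR distance between the circles within a block
#'
#' Aggregates the `dt`-resolution center distance of a block trajectory to
#' the TR grid. Only TRs fully inside the block emit values.
#'
#' @param traj block trajectory from [simulate_motion()] covering
#'   `schedule$block_s` seconds.
#' @param schedule an [build_schedule()] object.
#' @param run 0-based run index of the block.
#' @param block 1-based block index within the run.
#' @param rule aggregation over the samples of each TR: `"mean"` (default,
#'   least sensitive to sample-level jitter), `"onset"` (first sample), or
#'   `"min"`.
#' @return tibble with columns `run`, `block`, `tr_index` (0-based within
#'   run), `distance`.
#' @export
distance_per_tr <- function(traj, schedule, run = 0, block = 1,
                            rule = c("mean", "onset", "min")) {
  rule <- match.arg(rule)
  stopifnot(inherits(traj, "circle_trajectory"),
            inherits(schedule, "event_schedule"))
  per_tr <- schedule$tr / traj$dt
  if (abs(per_tr - round(per_tr)) > 1e-9) {
    stop("alignment error: TR is not a multiple of the trajectory dt")
  }
  per_tr <- as.integer(round(per_tr))
  n_tr <- as.integer(round(schedule$block_s / schedule$tr))
  if (traj$n_steps < n_tr * per_tr) {
    stop("alignment error: trajectory shorter than the block")
  }
  d <- .traj_distance(traj)
  grp <- rep(seq_len(n_tr), each = per_tr)
  val <- switch(rule,
    mean  = as.numeric(tapply(d[seq_along(grp)], grp, mean)),
    onset = d[(seq_len(n_tr) - 1) * per_tr + 1],
    min   = as.numeric(tapply(d[seq_along(grp)], grp, min)))
  onset_tr <- as.integer(round(schedule$block_onsets[block] / schedule$tr))
  tibble::tibble(run = as.integer(run), block = as.integer(block),
                 tr_index = onset_tr + seq_len(n_tr) - 1L, distance = val)
}

#' Simulate the full threat paradigm
#'
#' Runs the circle-motion simulation for every block of `schedule`, detects
#' collisions, and assembles shock events and the per-TR distance table. By
#' default the motion is purely random and collisions are emergent. With
#' `steering = TRUE`, a small attraction toward the other circle is active in
#' a scheduled subset of blocks until a target number of collisions has
#' occurred (8 per run spread over 4 of the blocks, at most 3 per block),
#' after which attraction is released; steered output is flagged in the
#' returned metadata.
#'
#' @param schedule an [build_schedule()] object.
#' @param momentum_c,noise_scale,bounds see [simulate_motion()].
#' @param radius circle radius used for collision detection. Default 0.04.
#' @param steering logical; engineer collision counts. Default `FALSE`.
#' @param target_collisions collisions per run under steering. Default 8.
#' @param attract steering attraction magnitude. Default 0.004.
#' @param rule distance aggregation rule, see [distance_per_tr()].
#' @param seed top-level integer seed; per-run/per-block substreams are
#'   derived from it deterministically.
#' @return list with `events` (tibble: run, onset, duration, trial_type in
#'   {block, shock}), `distance` (tibble: run, block, tr_index, distance),
#'   `shock_times` (list per run, seconds within run), `steered`, `seed`.
#' @export
simulate_paradigm <- function(schedule, momentum_c = 0.2, noise_scale = 0.015,
                              bounds = c(0, 0, 1, 1), radius = 0.04,
                              steering = FALSE, target_collisions = 8,
                              attract = 0.004,
                              rule = "mean", seed = 1) {
  stopifnot(inherits(schedule, "event_schedule"))
  events <- list(); dists <- list(); shocks <- vector("list", schedule$n_runs)
  for (r in seq_len(schedule$n_runs) - 1L) {
    run_shocks <- numeric(0)
    if (steering) {
      set.seed((seed + 7919L * (r + 1L)) %% 2147483629L)
      shock_blocks <- sort(sample(schedule$n_blocks, 4))
      quota <- rep(0L, schedule$n_blocks)
      # distribute target_collisions over the 4 blocks, max 3 each
      alloc <- rep(2L, 4)
      spare <- target_collisions - sum(alloc)
      i <- 1
      while (spare != 0) {
        step <- sign(spare)
        if (alloc[i] + step >= 1 && alloc[i] + step <= 3) {
          alloc[i] <- alloc[i] + step; spare <- spare - step
        }
        i <- i %% 4 + 1
      }
      quota[shock_blocks] <- alloc
    }
    for (b in seq_len(schedule$n_blocks)) {
      bseed <- (seed + 7919L * (r + 1L) + 104729L * b) %% 2147483629L
      want <- if (steering) quota[b] else 0L
      traj <- .simulate_block(schedule, momentum_c, noise_scale, bounds,
                              radius, want, attract, bseed)
      times <- detect_collisions(traj, radius)
      if (steering) times <- utils::head(times, want)
      onset <- schedule$block_onsets[b]
      run_shocks <- c(run_shocks, onset + times)
      events[[length(events) + 1]] <- tibble::tibble(
        run = r, onset = onset, duration = schedule$block_s,
        trial_type = "block")
      if (length(times)) {
        events[[length(events) + 1]] <- tibble::tibble(
          run = r, onset = onset + times, duration = 0.5,
          trial_type = "shock")
      }
      dists[[length(dists) + 1]] <-
        distance_per_tr(traj, schedule, run = r, block = b, rule = rule)
    }
    shocks[[r + 1L]] <- run_shocks
  }
  ev <- dplyr::arrange(dplyr::bind_rows(events), .data$run, .data$onset)
  list(events = ev, distance = dplyr::bind_rows(dists),
       shock_times = shocks, steered = steering, seed = seed)
}

# one block of motion; when `want` collisions are requested, attraction stays
# on until that many separate contact episodes have begun, with a short
# refractory separation after each
.simulate_block <- function(schedule, momentum_c, noise_scale, bounds,
                            radius, want, attract, seed) {
  if (want <= 0) {
    return(simulate_motion(schedule$block_s, dt = 0.05,
                           momentum_c = momentum_c,
                           noise_scale = noise_scale, bounds = bounds,
                           seed = seed))
  }
  set.seed(seed)
  dt <- 0.05
  n_steps <- as.integer(round(schedule$block_s / dt))
  refract <- as.integer(round(2 / dt))
  x <- cbind(c(0.25, 0.5), c(0.75, 0.5))
  x[1, ] <- bounds[1] + x[1, ] * (bounds[3] - bounds[1])
  x[2, ] <- bounds[2] + x[2, ] * (bounds[4] - bounds[2])
  d <- matrix(0, 2, 2)
  pos <- list(matrix(NA_real_, n_steps, 2), matrix(NA_real_, n_steps, 2))
  hits <- 0L; cool <- 0L; in_contact <- FALSE
  for (k in seq_len(n_steps)) {
    eps <- matrix(stats::rnorm(4), 2, 2)
    d <- (1 - momentum_c) * d + momentum_c * eps * noise_scale
    gap <- x[, 2] - x[, 1]
    len <- sqrt(sum(gap^2))
    if (len > 0) {
      u <- gap / len
      if (hits < want && cool == 0L) {        # seek contact
        d[, 1] <- d[, 1] + attract * u
        d[, 2] <- d[, 2] - attract * u
      } else if (cool > 0L) {                 # separate after a hit
        d[, 1] <- d[, 1] - attract * u
        d[, 2] <- d[, 2] + attract * u
      }
    }
    x <- x + d
    for (i in 1:2) for (j in 1:2) {
      lo <- bounds[j]; hi <- bounds[j + 2]
      if (x[j, i] < lo) { x[j, i] <- lo; d[j, i] <- -d[j, i] }
      if (x[j, i] > hi) { x[j, i] <- hi; d[j, i] <- -d[j, i] }
    }
    now_contact <- sqrt(sum((x[, 1] - x[, 2])^2)) <= 2 * radius
    if (now_contact && !in_contact && cool == 0L) {
      hits <- hits + 1L
      cool <- refract
    }
    in_contact <- now_contact
    if (cool > 0L) cool <- cool - 1L
    pos[[1]][k, ] <- x[, 1]
    pos[[2]][k, ] <- x[, 2]
  }
  structure(list(positions = pos, displacements = NULL, dt = dt,
                 momentum_c = momentum_c, bounds = bounds, steered = TRUE,
                 n_steps = n_steps),
            class = "circle_trajectory")
}

#' Write a BIDS-style events table
#'
#' @param events tibble with columns onset, duration, trial_type (and
#'   optionally run).
#' @param file output path; written tab-delimited with a header.
#' @return the path, invisibly.
#' @export
write_events <- function(events, file) {
  utils::write.table(events, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
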