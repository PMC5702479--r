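test_that("displacement follows the momentum AR(1) update", {
  # reconstruct the innovations from the recursion: with unbounded motion,
  # e_t = (d_t - (1 - c) d_{t-1}) / (c * noise_scale) must be iid N(0, 1)
  traj <- simulate_motion(500, dt = 0.05, momentum_c = 0.2,
                          noise_scale = 0.01, bounds = NULL, seed = 11)
  d <- traj$displacements[[1]][, 1]
  e <- (d[-1] - 0.8 * d[-length(d)]) / (0.2 * 0.01)
  expect_equal(sd(e), 1, tolerance = 0.05)
  expect_lt(abs(mean(e)), 3 / sqrt(length(e)))
  # momentum: lag-1 autocorrelation of the displacement approaches 1 - c
  long <- simulate_motion(2000, dt = 0.05, momentum_c = 0.2,
                          noise_scale = 1, bounds = NULL, seed = 12)
  dl <- long$displacements[[2]][, 2]
  expect_equal(cor(dl[-1], dl[-length(dl)]), 0.8, tolerance = 0.02)
})

test_that("motion is reproducible under a fixed seed and validates input", {
  a <- simulate_motion(10, seed = 3)
  b <- simulate_motion(10, seed = 3)
  expect_identical(a$positions, b$positions)
  expect_error(simulate_motion(10, momentum_c = 0), "momentum_c")
  expect_error(simulate_motion(10, momentum_c = NaN), "non-finite")
  expect_error(simulate_motion(0.01, dt = 0.05), "duration < dt")
  expect_error(simulate_motion(10, bounds = c(0, 0, 0, 1)), "bounds")
})

test_that("reflective bounds keep circles inside the screen", {
  traj <- simulate_motion(200, noise_scale = 0.1, bounds = c(0, 0, 1, 1),
                          seed = 4)
  for (p in traj$positions) {
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(is.finite(p)))
  }
})

test_that("schedule arithmetic is exact for any valid parameterization", {
  expect_identical(build_schedule()$vols_per_run, 457L)
  expect_identical(
    build_schedule(1, 1, rest_s = 0, block_s = 10, end_blank_s = 0)$
      vols_per_run, 10L)
  expect_identical(
    build_schedule(1, 2, rest_s = 15, block_s = 60,
                   end_blank_s = 7)$vols_per_run, 157L)
  expect_error(build_schedule(tr = 2), "multiples of TR")
})

test_that("collision detection collapses contact episodes into events", {
  # hand-built trajectory: circles approach on a line, touch at 0-based
  # sample 40 and stay in contact for 5 samples
  n <- 60
  gap <- c(seq(1, 0.2, length.out = 41), rep(0.05, 4),
           seq(0.2, 1, length.out = 15))
  p1 <- cbind(rep(0, n), rep(0, n))
  p2 <- cbind(gap, rep(0, n))
  traj <- structure(list(positions = list(p1, p2), dt = 0.05,
                         momentum_c = 0.2, bounds = NULL, n_steps = n),
                    class = "circle_trajectory")
  ev <- detect_collisions(traj, radius = 0.1)
  expect_identical(ev, 2.0)

  far <- structure(list(positions = list(p1, p1 + 5), dt = 0.05,
                        momentum_c = 0.2, bounds = NULL, n_steps = n),
                   class = "circle_trajectory")
  expect_identical(detect_collisions(far, radius = 0.1), numeric(0))
  expect_error(detect_collisions(traj, radius = -1), "radius")
})

test_that("per-TR distance aggregation covers in-block TRs only", {
  sched <- build_schedule(1, 1, rest_s = 5, block_s = 10, end_blank_s = 5,
                          tr = 1)
  n <- 10 / 0.05
  p1 <- cbind(rep(0, n), rep(0, n))
  p2 <- cbind(rep(3, n), rep(4, n))
  static <- structure(list(positions = list(p1, p2), dt = 0.05,
                           momentum_c = 0.2, bounds = NULL, n_steps = n),
                      class = "circle_trajectory")
  d <- distance_per_tr(static, sched, run = 0, block = 1)
  expect_equal(nrow(d), 10)
  expect_true(all(d$distance == 5))
  # block onset at 5 s: no TR before it emits a distance
  expect_identical(min(d$tr_index), 5L)
  expect_identical(max(d$tr_index), 14L)

  # circle 2 moves linearly from (3,4) to (6,8): TR-mean distance lies
  # strictly between the endpoint distances 5 and 10
  n1 <- 1 / 0.05
  sched1 <- build_schedule(1, 1, rest_s = 0, block_s = 1, end_blank_s = 0,
                           tr = 1)
  mv <- structure(list(positions = list(
    cbind(rep(0, n1), rep(0, n1)),
    cbind(seq(3, 6, length.out = n1), seq(4, 8, length.out = n1))),
    dt = 0.05, momentum_c = 0.2, bounds = NULL, n_steps = n1),
    class = "circle_trajectory")
  dm <- distance_per_tr(mv, sched1, run = 0, block = 1, rule = "mean")
  expect_gt(dm$distance, 5)
  expect_lt(dm$distance, 10)
})

test_that("full paradigm simulation is reproducible and well-formed", {
  sched <- build_schedule(n_runs = 1, n_blocks = 2)
  a <- simulate_paradigm(sched, seed = 9)
  b <- simulate_paradigm(sched, seed = 9)
  expect_identical(a$distance, b$distance)
  expect_identical(a$events, b$events)
  expect_false(a$steered)
  # distance rows: one per in-block TR
  expect_identical(nrow(a$distance), 2L * 60L)
  expect_true(all(a$distance$distance >= 0))
  expect_setequal(unique(a$events$trial_type),
                  intersect(c("block", "shock"),
                            unique(a$events$trial_type)))
})

test_that("steering engineers the scheduled number of collisions", {
  sched <- build_schedule(n_runs = 1, n_blocks = 6)
  sim <- simulate_paradigm(sched, steering = TRUE, seed = 2)
  expect_true(sim$steered)
  n_shocks <- length(sim$shock_times[[1]])
  expect_lte(n_shocks, 8L)
  expect_gte(n_shocks, 1L)
  # all shocks inside blocks
  sh <- sim$events[sim$events$trial_type == "shock", ]
  blk <- sim$events[sim$events$trial_type == "block", ]
  inside <- vapply(sh$onset, function(o) {
    any(o >= blk$onset & o < blk$onset + blk$duration)
  }, logical(1))
  expect_true(all(inside))
})
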