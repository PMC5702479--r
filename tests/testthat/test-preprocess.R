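test_that("nuisance design contains the expected columns", {
  sched <- build_schedule(1, 1, rest_s = 5, block_s = 20, end_blank_s = 5)
  m0 <- build_nuisance(sched, poly_order = 0)
  expect_identical(colnames(m0$design[[1]]), c("constant", "block"))

  m4 <- build_nuisance(sched, poly_order = 4)
  X <- m4$design[[1]]
  expect_identical(colnames(X),
                   c("constant", paste0("poly", 1:4), "block"))
  # per-run polynomials are mutually orthogonal
  P <- X[, paste0("poly", 1:4)]
  off <- crossprod(P) - diag(diag(crossprod(P)))
  expect_lt(max(abs(off)), 1e-10)

  # constant motion has zero derivative columns
  mot <- matrix(0.7, sched$vols_per_run, 6)
  mm <- build_nuisance(sched, motion = mot)
  expect_true(all(mm$design[[1]][, paste0("dmotion", 1:6)] == 0))
  expect_error(build_nuisance(sched, motion = mot[-1, ]), "alignment")
})

test_that("block regressor is a delayed, HRF-shaped response", {
  # impulse response peaks at the HRF peak latency
  k <- hrf_kernel(tr = 0.1)
  expect_equal((which.max(k) - 1) * 0.1, 6, tolerance = 0.11)
  expect_equal(max(k), 1, tolerance = 1e-3)
  # block regressor rises only after block onset and peaks several
  # seconds into the block
  sched <- build_schedule(1, 1, rest_s = 15, block_s = 60, end_blank_s = 7)
  X <- build_nuisance(sched)$design[[1]]
  b <- X[, "block"]
  expect_true(all(abs(b[1:15]) < 1e-6))
  peak_delay <- which.max(b) - 1 - 15   # TRs after block onset
  expect_gte(peak_delay, 5)
  expect_lte(peak_delay, 20)
})

test_that("regression annihilates the design space and z-scores per run", {
  sched <- build_schedule(2, 2, rest_s = 5, block_s = 20, end_blank_s = 5)
  model <- build_nuisance(sched, poly_order = 4)
  L <- sched$vols_per_run
  X <- model$design[[1]]
  set.seed(21)
  S <- 3; R <- 4
  data <- array(rnorm(S * R * 2 * L), c(S, R, 2 * L))
  # subject 1, ROI 1 equals a design column; ROI 2 carries injected drift
  drift <- X[, "poly4"]
  data[1, 1, 1:L] <- X[, "block"]
  data[1, 2, 1:L] <- data[1, 2, 1:L] + 5 * drift
  series <- roi_ts(data, paste0("r", 1:R), sched$tr, rep(L, 2))

  res <- regress_out(series, model, zscore = FALSE)
  expect_identical(res$stage, "residual")
  expect_lt(max(abs(res$data[1, 1, 1:L])), 1e-8)
  expect_lt(abs(cor(res$data[1, 2, 1:L], drift)), 1e-10)
  # residuals orthogonal to every design column
  cors <- abs(cor(res$data[2, 3, 1:L], X[, -1]))
  expect_lt(max(cors), 1e-10)

  z <- regress_out(series, model)
  expect_identical(z$stage, "zscored")
  for (r in 1:2) {
    idx <- ((r - 1) * L + 1):(r * L)
    expect_lt(abs(mean(z$data[2, 2, idx])), 1e-8)
    expect_equal(sd(z$data[2, 2, idx]), 1, tolerance = 1e-8)
  }
  expect_error(regress_out(z, model), "raw")
})

test_that("rank-deficient designs fail naming the collinear columns", {
  sched <- build_schedule(1, 1, rest_s = 5, block_s = 20, end_blank_s = 5)
  mot <- matrix(0.7, sched$vols_per_run, 6)  # constant: collinear
  model <- build_nuisance(sched, motion = mot)
  set.seed(5)
  series <- roi_ts(array(rnorm(3 * 2 * sched$vols_per_run),
                         c(3, 2, sched$vols_per_run)),
                   c("r1", "r2"), 1, sched$vols_per_run)
  expect_error(regress_out(series, model), "collinear")
})

test_that("condition labeling applies every censoring rule", {
  # 30-TR block, one shock at t = 10 s, hand-enumerated labels
  sched <- build_schedule(1, 1, rest_s = 0, block_s = 30, end_blank_s = 0)
  d <- c(10, 9.5, 9, 8.5, 8, 7.5, 7, 6.5, 6, 5.5,    # TR 0..9
         5, 4.5, 4, 3.5, 3, 2.5, 2, 1.5, 1, 0.5,     # TR 10..19
         1, 1.5, 2, 2.5, 3, 3.5, 3, 2.5, 2, 2)       # TR 20..29
  dist <- tibble::tibble(run = 0L, block = 1L, tr_index = 0:29,
                         distance = d)
  lab <- label_conditions(dist, sched, shock_times = list(10),
                          cutoff_fraction = 0.75)
  # TR 0..14: block onset skip; TR 10..24 post-shock (10..14 already onset)
  expect_true(all(lab$reason[1:15] == "block_onset"))
  expect_true(all(lab$reason[16:25] == "post_shock"))
  # max distance 10, gate keeps distance <= 7.5: TRs 25..29 all pass
  # deltas: TR25 3.5-3=+0.5 retreat; TR26 -0.5 approach; TR27 -0.5;
  # TR28 -0.5; TR29 0 tie
  expect_identical(lab$label[26:30],
                   c("retreat", "approach", "approach", "approach",
                     "excluded"))
  expect_identical(lab$reason[30], "tie")
  # label counts conserved
  expect_identical(sum(lab$label == "approach") +
                     sum(lab$label == "retreat") +
                     sum(lab$label == "excluded"), 30L)
})

test_that("the proximity gate obeys its direction and boundary case", {
  sched <- build_schedule(1, 1, rest_s = 0, block_s = 10, end_blank_s = 0)
  d <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  dist <- tibble::tibble(run = 0L, block = 1L, tr_index = 0:9,
                         distance = d)
  lab <- label_conditions(dist, sched, shock_times = list(numeric(0)),
                          cutoff_fraction = 0.5, onset_skip_s = 0)
  # near gate: distance <= 5 retained; TR 0 has no delta -> tie
  expect_identical(lab$reason[1], "tie")
  expect_true(all(lab$label[2:5] == "retreat"))
  expect_true(all(lab$reason[6:10] == "distance_cutoff"))

  far <- label_conditions(dist, sched, shock_times = list(numeric(0)),
                          cutoff_fraction = 0.5, onset_skip_s = 0,
                          gate = "far")
  # threshold 5 is attained at TR 4; TRs 0..3 fail the far gate
  expect_true(all(far$label[5:10] == "retreat"))
  expect_true(all(far$reason[1:4] == "distance_cutoff"))

  # cutoff 1.0: the TR attaining the maximum is retained by the gate
  g1 <- label_conditions(dist, sched, shock_times = list(numeric(0)),
                         cutoff_fraction = 1.0, onset_skip_s = 0)
  expect_identical(g1$label[10], "retreat")
  expect_error(label_conditions(dist, sched, list(numeric(0)),
                                cutoff_fraction = 1.5), "cutoff_fraction")
})

test_that("exclusion rules commute: the excluded set is a union", {
  sched <- build_schedule(1, 2, rest_s = 5, block_s = 30, end_blank_s = 5)
  set.seed(31)
  sim <- simulate_paradigm(sched, seed = 31)
  shocks <- list(c(20, 50))
  full <- label_conditions(sim$distance, sched, shocks)
  # each rule alone
  only_shock <- label_conditions(sim$distance, sched, shocks,
                                 cutoff_fraction = 1, onset_skip_s = 0)
  only_onset <- label_conditions(sim$distance, sched,
                                 list(numeric(0)), cutoff_fraction = 1)
  only_gate <- label_conditions(sim$distance, sched, list(numeric(0)),
                                onset_skip_s = 0)
  excl <- function(l, why) which(l$label == "excluded" & l$reason == why)
  manual <- sort(unique(c(
    which(is.na(full$distance)),                        # rest
    excl(only_shock, "post_shock"), excl(only_onset, "block_onset"),
    excl(only_gate, "distance_cutoff"), excl(full, "tie"))))
  expect_setequal(which(full$label == "excluded"), manual)
  # relabeling with identical inputs is idempotent
  again <- label_conditions(sim$distance, sched, shocks)
  expect_identical(full$label, again$label)
  expect_identical(full$reason, again$reason)
})
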