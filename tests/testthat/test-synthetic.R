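test_that("coupling matrices follow the linear ramp and unit diagonal", {
  part <- two_net_partition()
  cs <- coupling_spec(data.frame(n1 = "net1", n2 = "net1", base = 0.3,
                                 approach_slope = 0.05,
                                 retreat_slope = -0.02))
  M <- iscnet:::.coupling_matrix(part, cs, "approach", 4)
  expect_equal(M["a1", "a2"], 0.5)       # 0.3 + 0.05 * 4
  expect_equal(unname(diag(M)), rep(1, 6))
  expect_equal(M["a1", "b1"], 0)         # default base
  Mr <- iscnet:::.coupling_matrix(part, cs, "retreat", 5)
  expect_equal(Mr["a1", "a3"], 0.2)
})

test_that("invalid coupling configurations fail loudly with context", {
  part <- two_net_partition()
  hot <- coupling_spec(data.frame(n1 = "net1", n2 = "net1", base = 0.9,
                                  approach_slope = 0.05,
                                  retreat_slope = 0))
  expect_error(generator_config(part, 5, coupling = hot),
               "out of \\[-1, 1\\].*net1")
  # negative equicorrelation below the PSD limit
  neg <- coupling_spec(data.frame(n1 = "net1", n2 = "net1", base = -0.6,
                                  approach_slope = 0,
                                  retreat_slope = 0))
  expect_error(generator_config(part, 5, coupling = neg),
               "positive semi-definite")
  expect_error(generator_config(part, 2), "n_subjects")
})

test_that("expected ISC follows the leave-one-out closed form", {
  part <- two_net_partition()
  pure <- generator_config(part, 5, shared_variance = 1, noise_sd = 0)
  expect_equal(unname(diag(expected_isc(pure))), rep(1, 6))
  cfg <- generator_config(part, 21, shared_variance = 1, noise_sd = 1)
  # v / (sqrt(v + s2) * sqrt(v + s2/(N-1))) at v = s2 = 1, N = 21
  expect_equal(unname(diag(expected_isc(cfg))[1]),
               1 / (sqrt(2) * sqrt(1 + 1 / 20)))
  expect_equal(unname(diag(expected_isc(cfg))[1]), 0.690,
               tolerance = 5e-4)
  # off-diagonal scales with the coupling at the requested time
  cs <- coupling_spec(data.frame(n1 = "net1", n2 = "net1", base = 0.2,
                                 approach_slope = 0.05,
                                 retreat_slope = 0))
  cfgc <- generator_config(part, 21, coupling = cs)
  E <- expected_isc(cfgc, "approach", tau = 2)
  expect_equal(E["a1", "a2"], 0.3 / (sqrt(2) * sqrt(1.05)))
})

test_that("generated datasets are reproducible and ground truth consistent", {
  sched <- build_schedule(1, 2, rest_s = 5, block_s = 30, end_blank_s = 5)
  lab <- synthetic_labels(sched, rep(6L, 3), rep(6L, 3), onset_skip_s = 5)
  part <- two_net_partition()
  cs <- coupling_spec(data.frame(n1 = "net1", n2 = "net1", base = 0.2,
                                 approach_slope = 0.03,
                                 retreat_slope = -0.03))
  cfg <- generator_config(part, 4, coupling = cs, seed = 77)
  g1 <- generate_dataset(cfg, sched, lab)
  g2 <- generate_dataset(cfg, sched, lab)
  expect_identical(g1$series$data, g2$series$data)
  expect_identical(dim(g1$series$data), c(4L, 6L, sched$total_vols))
  tr <- g1$truth
  expect_equal(tr$expected_diag_isc,
               1 / (sqrt(2) * sqrt(1 + 1 / 3)))
  sl <- tr$slopes
  expect_equal(sl$isc_slope[sl$condition == "approach"],
               0.03 * tr$isc_scale)
  expect_equal(sl$coupling_slope[sl$condition == "retreat"], -0.03)
})

test_that("injected nuisance components are recovered by regression", {
  sched <- build_schedule(1, 2, rest_s = 5, block_s = 30, end_blank_s = 5)
  lab <- synthetic_labels(sched, rep(6L, 3), rep(6L, 3), onset_skip_s = 5)
  part <- two_net_partition()
  cfg <- generator_config(part, 4, drift_amp = 2, motion_amp = 2,
                          block_amp = 3, seed = 11)
  gen <- generate_dataset(cfg, sched, lab)
  clean <- regress_out(gen$series, build_nuisance(sched), zscore = FALSE)
  L <- sched$vols_per_run
  # residuals are orthogonal to the injected motion regressors
  for (s in 1:2) {
    M <- gen$series$motion[[s]][1:L, ]
    for (i in 1:2) {
      expect_lt(max(abs(cor(clean$data[s, i, 1:L], M))), 1e-10)
    }
  }
  # and to the block-evoked shape
  X <- build_nuisance(sched)$design[[1]]
  expect_lt(abs(cor(clean$data[1, 1, 1:L], X[, "block"])), 1e-10)
})

test_that("noise-free identical shared signal yields unit diagonal ISC", {
  sched <- build_schedule(1, 1, rest_s = 0, block_s = 60, end_blank_s = 0)
  lab <- synthetic_labels(sched, rep(10L, 2), rep(10L, 2),
                          onset_skip_s = 0)
  part <- two_net_partition()
  cfg <- generator_config(part, 4, shared_variance = 1, noise_sd = 0,
                          drift_amp = 0, motion_amp = 0, block_amp = 0)
  gen <- generate_dataset(cfg, sched, lab, seed = 2)
  z <- regress_out(gen$series, build_nuisance(sched, poly_order = 0))
  m <- ism_subject(z, 1, 1:60)
  expect_equal(unname(diag(unclass(m))), rep(1, 6), tolerance = 1e-10)
})

test_that("synthetic labels honor the schedule and segment queues", {
  sched <- build_schedule(2, 2, rest_s = 10, block_s = 40, end_blank_s = 5)
  lab <- synthetic_labels(sched, rep(7L, 6), rep(5L, 6), onset_skip_s = 10)
  expect_identical(nrow(lab), sched$total_vols)
  segs <- extract_segments(lab)
  expect_identical(sum(segs$condition == "approach"), 6L)
  expect_identical(sum(segs$condition == "retreat"), 6L)
  expect_true(all(segs$length[segs$condition == "approach"] == 7L))
  expect_true(all(segs$length[segs$condition == "retreat"] == 5L))
  # no segment TR falls in rest or the onset-skip window
  expect_true(all(lab$reason[lab$label != "excluded"] %in% NA))
  expect_error(synthetic_labels(sched, rep(50L, 40), rep(50L, 40)),
               "too short")
})
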