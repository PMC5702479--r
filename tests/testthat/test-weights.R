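test_that("the packaged partition matches the published network sizes", {
  p <- default_partition()
  counts <- table(p$network)
  expect_identical(unname(counts[["salience"]]), 13L)
  expect_identical(unname(counts[["executive"]]), 12L)
  expect_identical(unname(counts[["task_negative"]]), 12L)
  expect_identical(unname(counts[["subcortical"]]), 10L)
  expect_identical(anyDuplicated(p$roi), 0L)
})

test_that("network weights match hand computations", {
  part <- tibble::tibble(roi = c("a", "b", "c"),
                         network = c("N1", "N1", "N2"))
  M <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"),
                                       c("a", "b", "c")))
  M["a", "c"] <- M["c", "a"] <- 0.2
  M["b", "c"] <- M["c", "b"] <- 0.4
  ism <- toy_ism(M)
  expect_equal(as.numeric(network_weight(ism, "N1", "N2", part)), 0.3)
  expect_identical(as.numeric(network_weight(ism, "N1", "N2", part,
                                             mode = "negative")), 0)

  # within-network with diagonal: (0.5 + 0.5 + 0.1 + 0.1) / 4 = 0.3
  W <- matrix(c(0.5, 0.1, 0.1, 0.5), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  pw <- tibble::tibble(roi = c("a", "b"), network = "N")
  expect_equal(as.numeric(network_weight(toy_ism(W), "N", "N", pw)), 0.3)
  # diagonal excluded: (0.1 + 0.1) / (4 - 2) = 0.1
  expect_equal(as.numeric(network_weight(toy_ism(W), "N", "N", pw,
                                         include_diagonal = FALSE)), 0.1)
  expect_error(network_weight(ism, "N1", "missing", part), "empty network")
})

test_that("weight invariants: symmetry, decomposition, scale", {
  set.seed(41)
  part <- two_net_partition(4, 3)
  M <- matrix(rnorm(49), 7, 7); M <- (M + t(M)) / 2
  dimnames(M) <- list(part$roi, part$roi)
  ism <- toy_ism(M)
  for (mode in c("positive", "negative", "all")) {
    expect_equal(as.numeric(network_weight(ism, "net1", "net2", part,
                                           mode = mode)),
                 as.numeric(network_weight(ism, "net2", "net1", part,
                                           mode = mode)),
                 tolerance = 1e-15)
  }
  for (n2 in c("net1", "net2")) {
    wp <- as.numeric(network_weight(ism, "net1", n2, part, "positive"))
    wn <- as.numeric(network_weight(ism, "net1", n2, part, "negative"))
    wa <- as.numeric(network_weight(ism, "net1", n2, part, "all"))
    expect_gte(wp, 0); expect_lte(wn, 0)
    expect_lt(abs(wa - (wp + wn)), 1e-12)
  }
  lam <- 2.5
  expect_equal(as.numeric(network_weight(toy_ism(lam * M), "net1", "net2",
                                         part)),
               lam * as.numeric(network_weight(ism, "net1", "net2", part)),
               tolerance = 1e-12)
})

test_that("subcortical index is a raw sum over target-network links", {
  nets <- tibble::tibble(
    roi = c(paste0("sal", 1:13), "pag"),
    network = c(rep("salience", 13), "subcortical"))
  M <- matrix(0, 14, 14, dimnames = list(nets$roi, nets$roi))
  M["pag", paste0("sal", 1:13)] <- 0.1
  M[paste0("sal", 1:13), "pag"] <- 0.1
  ism <- toy_ism(M)
  idx <- subcortical_index(ism, "pag", "salience", nets)
  expect_equal(as.numeric(idx), 1.3)
  expect_equal(attr(idx, "normalized"), 0.1)
  # equals n_target times the singleton network weight
  pw <- dplyr::bind_rows(nets[-14, ],
                         tibble::tibble(roi = "pag", network = "pagnet"))
  w <- network_weight(ism, "pagnet", "salience", pw)
  expect_equal(as.numeric(idx), 13 * as.numeric(w), tolerance = 1e-12)
  # all-negative entries yield zero in positive mode
  Mn <- M * -1
  expect_identical(as.numeric(subcortical_index(toy_ism(Mn), "pag",
                                                "salience", nets)), 0)
  expect_error(subcortical_index(ism, "sal1", "salience", nets),
               "belongs to the target")
})

test_that("weight trajectories reduce dynamic ISMs pair by pair", {
  part <- two_net_partition(2, 2)
  mk <- function(val, cond, t) {
    M <- matrix(val, 4, 4, dimnames = list(part$roi, part$roi))
    iscnet:::.new_ism(M, part$roi, "group", TRUE, 20L, condition = cond,
                      t = t)
  }
  isms <- list(approach = list(`0` = mk(0, "approach", 0),
                               `1` = mk(0.2, "approach", 1)),
               retreat = list(`0` = mk(-0.1, "retreat", 0)))
  traj <- weight_trajectories(isms, part)
  z <- traj[traj$condition == "approach" & traj$t == 0, ]
  expect_true(all(z$weight == 0))
  a1 <- traj[traj$condition == "approach" & traj$t == 1 &
               traj$mode == "positive", ]
  expect_true(all(a1$weight == 0.2))
  r0 <- traj[traj$condition == "retreat" & traj$mode == "positive", ]
  expect_true(all(r0$weight == 0))
  rn <- traj[traj$condition == "retreat" & traj$mode == "negative", ]
  expect_true(all(rn$weight == -0.1))
  expect_identical(unique(traj$n_samples), 20L)
})
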