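# fixtures and independent oracles used across the suite

# naive two-loop leave-one-out ISM: the independent oracle for isc_core
naive_ism_subject <- function(data, subject, sample_index) {
  S <- dim(data)[1]; R <- dim(data)[2]
  M <- matrix(NA_real_, R, R)
  others <- setdiff(seq_len(S), subject)
  for (i in seq_len(R)) {
    yi <- data[subject, i, sample_index]
    for (j in seq_len(R)) {
      yj <- colMeans(data[others, j, sample_index, drop = FALSE][, 1, ])
      M[i, j] <- suppressWarnings(cor(yi, yj))
    }
  }
  M
}

naive_ism_group <- function(data, sample_index) {
  S <- dim(data)[1]
  Ms <- lapply(seq_len(S), function(s) naive_ism_subject(data, s,
                                                         sample_index))
  G <- Reduce(`+`, Ms) / S
  (G + t(G)) / 2
}

# white-noise z-scored multi-subject series (single run)
make_noise_ts <- function(S, R, T, seed = 1) {
  set.seed(seed)
  data <- array(rnorm(S * R * T), c(S, R, T))
  for (s in seq_len(S)) for (i in seq_len(R)) {
    x <- data[s, i, ]
    data[s, i, ] <- (x - mean(x)) / sd(x)
  }
  roi_ts(data, paste0("roi", seq_len(R)), tr = 1, run_lens = T,
         stage = "zscored")
}

# all subjects carry the identical signal (diagonal ISC must be 1)
make_identical_ts <- function(S, R, T, seed = 1) {
  set.seed(seed)
  sig <- matrix(rnorm(R * T), R, T)
  data <- array(NA_real_, c(S, R, T))
  for (s in seq_len(S)) data[s, , ] <- sig
  roi_ts(data, paste0("roi", seq_len(R)), tr = 1, run_lens = T,
         stage = "zscored")
}

# a group-kind ism from a plain matrix (for toy weight computations)
toy_ism <- function(M, rois = rownames(M)) {
  if (is.null(rois)) rois <- paste0("r", seq_len(nrow(M)))
  iscnet:::.new_ism(M, rois, "group", TRUE, sample_count = 10L)
}

two_net_partition <- function(n1 = 3, n2 = 3) {
  tibble::tibble(roi = c(paste0("a", seq_len(n1)),
                         paste0("b", seq_len(n2))),
                 network = c(rep("net1", n1), rep("net2", n2)))
}

# minimal labels tibble from a label character vector (single run)
labels_from_vector <- function(lab, run = 0L) {
  tibble::tibble(run = run, tr_index = seq_along(lab) - 1L, label = lab,
                 reason = ifelse(lab == "excluded", "tie", NA_character_),
                 distance = NA_real_)
}
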