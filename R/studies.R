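# Simulation studies validating the statistical guarantees of the pipeline
# on synthetic data with known ground truth. These are the package's own
# calibration benchmarks; their defaults define the study conditions
# (geometry chosen to mirror the per-slice sample counts a full-size
# acquisition yields, at a size a desktop machine runs in minutes).

# shared fixtures -------------------------------------------------------------

.study_partition <- function(n1 = 3, n2 = 3, name1 = "net1",
                             name2 = "net2") {
  tibble::tibble(
    roi = c(paste0("a", seq_len(n1)), paste0("b", seq_len(n2))),
    network = c(rep(name1, n1), rep(name2, n2)))
}

# residualize + z-score a generated dataset with the matching nuisance model
.study_clean <- function(gen, schedule) {
  regress_out(gen$series, build_nuisance(schedule))
}

#' Type-I error calibration of the circular-shift slope test
#'
#' Generates null datasets (by default pure subject-specific noise plus
#' nuisance components: no stimulus-locked signal, no coupling, and in
#' particular no condition-dependent coupling change, so the slope null is
#' true and the data are exchangeable under circular shifts), runs the full
#' dynamic-ISC -> weight -> slope pipeline and the circular-shift
#' permutation test on each, and reports the rejection rate of the
#' within-network approach-slope test at the nominal level.
#'
#' Each dataset has 8 subjects and 6 ROIs in two networks on a 2-run,
#' 4-block schedule carrying 20 approach and 20 retreat segments of 8 TRs,
#' so every retained slice (t = 0..2 s after the 5-s lag) holds exactly the
#' minimum 20 samples.
#'
#' Setting `shared_variance > 0` adds an uncoupled stimulus-locked
#' component shared across subjects. The slope null still holds, but the
#' data are then no longer exchangeable under circular shifts -- shifting
#' destroys the shared component, so the null understates the sampling
#' variability of the aligned correlations and the test becomes
#' anti-conservative. The parameter is exposed so this sensitivity can be
#' measured directly; see the methods vignette.
#'
#' @param n_datasets number of null datasets. Default 200.
#' @param n_realizations circular-shift realizations per dataset. Default
#'   500.
#' @param shared_variance variance of the (uncoupled) stimulus-locked
#'   component. Default 0 (exchangeable null).
#' @param alpha nominal level. Default 0.05.
#' @param seed integer seed.
#' @return list with `rejection_rate`, `p_values`, `n_datasets`,
#'   `n_realizations`.
#' @export
calibration_study <- function(n_datasets = 200, n_realizations = 500,
                              shared_variance = 0, alpha = 0.05,
                              seed = 1) {
  schedule <- build_schedule(n_runs = 2, n_blocks = 4, rest_s = 15,
                             block_s = 60, end_blank_s = 7, tr = 1)
  labels <- synthetic_labels(schedule, rep(8L, 20), rep(8L, 20))
  part <- .study_partition()
  seg <- build_slices(extract_segments(labels), lag_s = 5,
                      min_samples = 20, tr = 1)
  pair <- data.frame(n1 = "net1", n2 = "net1")
  cfg <- generator_config(part, n_subjects = 8,
                          shared_variance = shared_variance,
                          coupling = coupling_spec(), noise_sd = 1)
  p_values <- numeric(n_datasets)
  for (i in seq_len(n_datasets)) {
    gen <- generate_dataset(cfg, schedule, labels,
                            seed = (seed + 7717L * i) %% 2147483629L)
    clean <- .study_clean(gen, schedule)
    traj <- weight_trajectories(ism_dynamic(clean, seg), part,
                                pairs = pair, modes = "positive")
    null <- suppressWarnings(circular_null(
      clean, seg, part, pairs = pair, modes = "positive",
      n_realizations = n_realizations,
      seed = (seed + 104729L * i) %% 2147483629L))
    res <- test_slopes(traj, null)
    p_values[i] <- res$slopes$p_value[
      res$slopes$condition == "approach"]
  }
  list(rejection_rate = mean(p_values < alpha), p_values = p_values,
       n_datasets = n_datasets, n_realizations = n_realizations)
}

#' Parameter-recovery study for condition-dependent coupling
#'
#' Generates datasets in which the within-network coupling of the shared
#' innovations ramps up during approach and down during retreat (by default
#' +/- 0.025 correlation units per second, i.e. an expected ISC change of
#' about 0.1 over 6 s for 20 subjects at unit signal and noise variance),
#' runs the pipeline, and reports how often the estimated approach and
#' retreat slopes of the within-network positive weight recover the true
#' signs and how often the circular-shift approach-slope test rejects.
#'
#' The default geometry uses the ramped network at its published size (13
#' ROIs, the salience-network count) and a full 6-run, 6-block schedule
#' carrying 54 approach and 54 retreat segments of 12 TRs each, yielding
#' slices t = 0..6 s in both conditions after the 5-s lag -- per-slice
#' sample counts comparable to a full-size acquisition.
#'
#' @param n_sims number of simulated datasets. Default 50.
#' @param n_realizations circular-shift realizations per dataset. Default
#'   199.
#' @param n_subjects subjects per dataset. Default 20.
#' @param coupling_slope within-network coupling change per second during
#'   approach (mirrored negatively during retreat). Default 0.025.
#' @param alpha nominal level of the slope test. Default 0.05.
#' @param seed integer seed.
#' @return list with `approach_reject_rate`, `sign_match_rate` (both slopes
#'   correct), `approach_sign_rate`, `retreat_sign_rate`, `true_isc_slope`
#'   (expected ISC change per second), and the per-sim slopes/p-values.
#' @export
recovery_study <- function(n_sims = 50, n_realizations = 199,
                           n_subjects = 20, coupling_slope = 0.025,
                           alpha = 0.05, seed = 1) {
  schedule <- build_schedule()
  labels <- synthetic_labels(schedule, rep(12L, 54), rep(12L, 54))
  part <- .study_partition(13, 3)
  seg <- build_slices(extract_segments(labels), lag_s = 5,
                      min_samples = 20, tr = 1)
  pair <- data.frame(n1 = "net1", n2 = "net1")
  cs <- coupling_spec(data.frame(
    n1 = "net1", n2 = "net1", base = 0.3,
    approach_slope = coupling_slope, retreat_slope = -coupling_slope))
  cfg <- generator_config(part, n_subjects = n_subjects,
                          shared_variance = 1, coupling = cs,
                          noise_sd = 1)
  out <- tibble::tibble(sim = seq_len(n_sims), approach_slope = NA_real_,
                        retreat_slope = NA_real_, p_approach = NA_real_)
  true_isc_slope <- NA_real_
  for (i in seq_len(n_sims)) {
    gen <- generate_dataset(cfg, schedule, labels,
                            seed = (seed + 7717L * i) %% 2147483629L)
    true_isc_slope <- gen$truth$slopes$isc_slope[
      gen$truth$slopes$condition == "approach"]
    clean <- .study_clean(gen, schedule)
    traj <- weight_trajectories(ism_dynamic(clean, seg), part,
                                pairs = pair, modes = "positive")
    null <- suppressWarnings(circular_null(
      clean, seg, part, pairs = pair, modes = "positive",
      n_realizations = n_realizations,
      seed = (seed + 104729L * i) %% 2147483629L))
    res <- test_slopes(traj, null)
    out$approach_slope[i] <-
      res$slopes$slope[res$slopes$condition == "approach"]
    out$retreat_slope[i] <-
      res$slopes$slope[res$slopes$condition == "retreat"]
    out$p_approach[i] <-
      res$slopes$p_value[res$slopes$condition == "approach"]
  }
  list(approach_reject_rate = mean(out$p_approach < alpha),
       sign_match_rate = mean(out$approach_slope > 0 &
                                out$retreat_slope < 0),
       approach_sign_rate = mean(out$approach_slope > 0),
       retreat_sign_rate = mean(out$retreat_slope < 0),
       true_isc_slope = true_isc_slope,
       results = out, n_sims = n_sims,
       n_realizations = n_realizations)
}
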