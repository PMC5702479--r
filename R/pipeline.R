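#' Validated configuration for the end-to-end pipeline
#'
#' Collects every stage's parameters, validates them before any computation,
#' and records them (resolved) alongside each pipeline run.
#'
#' @param n_runs,n_blocks,rest_s,block_s,end_blank_s,tr schedule, see
#'   [build_schedule()].
#' @param momentum_c,noise_scale,radius,steering paradigm simulation, see
#'   [simulate_paradigm()].
#' @param n_subjects,shared_variance,noise_sd,drift_amp,motion_amp,block_amp
#'   generator, see [generator_config()].
#' @param coupling a [coupling_spec()].
#' @param cutoff_fraction,onset_skip_s,shock_window_s,gate labeling, see
#'   [label_conditions()].
#' @param lag_s,min_samples slicing, see [build_slices()].
#' @param modes weight modes evaluated.
#' @param include_diagonal see [network_weight()].
#' @param n_realizations permutation realizations, see [circular_null()].
#' @param partition partition tibble; default [default_partition()].
#' @param seed top-level seed funnelling every source of randomness.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_runs = 2, n_blocks = 6, rest_s = 15,
                            block_s = 60, end_blank_s = 7, tr = 1.0,
                            momentum_c = 0.2, noise_scale = 0.015,
                            radius = 0.04, steering = FALSE,
                            n_subjects = 8, shared_variance = 1,
                            coupling = coupling_spec(), noise_sd = 1,
                            drift_amp = 0.5, motion_amp = 0.5,
                            block_amp = 1,
                            cutoff_fraction = 0.75, onset_skip_s = 15,
                            shock_window_s = 15, gate = "near",
                            lag_s = 5, min_samples = 20,
                            modes = "positive", include_diagonal = TRUE,
                            n_realizations = 1000,
                            partition = NULL, seed = 1) {
  if (!is.numeric(cutoff_fraction) || cutoff_fraction <= 0 ||
      cutoff_fraction > 1) {
    stop("config validation error: cutoff_fraction must be in (0, 1]")
  }
  if (momentum_c <= 0 || momentum_c > 1) {
    stop("config validation error: momentum_c must be in (0, 1]")
  }
  if (min_samples < 2) {
    stop("config validation error: min_samples must be at least 2")
  }
  if (n_subjects < 3) {
    stop("config validation error: need at least 3 subjects")
  }
  modes <- match.arg(modes, c("positive", "negative", "all"),
                     several.ok = TRUE)
  if (is.null(partition)) partition <- default_partition()
  structure(
    list(n_runs = n_runs, n_blocks = n_blocks, rest_s = rest_s,
         block_s = block_s, end_blank_s = end_blank_s, tr = tr,
         momentum_c = momentum_c, noise_scale = noise_scale,
         radius = radius, steering = steering,
         n_subjects = n_subjects, shared_variance = shared_variance,
         coupling = coupling, noise_sd = noise_sd, drift_amp = drift_amp,
         motion_amp = motion_amp, block_amp = block_amp,
         cutoff_fraction = cutoff_fraction, onset_skip_s = onset_skip_s,
         shock_window_s = shock_window_s, gate = gate, lag_s = lag_s,
         min_samples = min_samples, modes = modes,
         include_diagonal = include_diagonal,
         n_realizations = n_realizations, partition = partition,
         seed = seed),
    class = "pipeline_config")
}

#' Run the full pipeline: simulate, generate, preprocess, slice, correlate,
#' weigh, infer
#'
#' Chains every stage on synthetic data and writes all intermediate and
#' final artifacts (events, distances, labels, segment index, per-slice
#' ISMs, weight trajectories, slope tests) plus the resolved configuration
#' and provenance to `out_dir`. With a fixed seed the statistical outputs
#' are byte-identical across invocations.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return (invisibly) a list with the in-memory stage results and the
#'   output directory.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  schedule <- build_schedule(config$n_runs, config$n_blocks, config$rest_s,
                             config$block_s, config$end_blank_s, config$tr)
  sim <- simulate_paradigm(schedule, momentum_c = config$momentum_c,
                           noise_scale = config$noise_scale,
                           radius = config$radius,
                           steering = config$steering, seed = config$seed)
  write_events(sim$events, file.path(out_dir, "events.tsv"))
  utils::write.table(
    data.frame(run = sim$distance$run, TR_index = sim$distance$tr_index,
               distance = sim$distance$distance),
    file.path(out_dir, "distance.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  labels <- label_conditions(sim$distance, schedule, sim$shock_times,
                             cutoff_fraction = config$cutoff_fraction,
                             onset_skip_s = config$onset_skip_s,
                             shock_window_s = config$shock_window_s,
                             gate = config$gate)
  write_labels(labels, file.path(out_dir, "labels.tsv"))

  gen_cfg <- generator_config(config$partition, config$n_subjects,
                              shared_variance = config$shared_variance,
                              coupling = config$coupling,
                              noise_sd = config$noise_sd,
                              drift_amp = config$drift_amp,
                              motion_amp = config$motion_amp,
                              block_amp = config$block_amp,
                              seed = config$seed + 1L)
  gen <- generate_dataset(gen_cfg, schedule, labels)
  write_roi_ts(gen$series, file.path(out_dir, "timeseries_raw"))
  jsonlite::write_json(gen$truth,
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)

  model <- build_nuisance(schedule)
  clean <- regress_out(gen$series, model)
  write_roi_ts(clean, file.path(out_dir, "timeseries_clean"))

  segs <- extract_segments(labels)
  seg <- build_slices(segs, lag_s = config$lag_s,
                      min_samples = config$min_samples, tr = config$tr)
  write_segment_index(seg, file.path(out_dir, "segment_index.json"))

  isms <- ism_dynamic(clean, seg)
  ism_dir <- file.path(out_dir, "isms")
  dir.create(ism_dir, showWarnings = FALSE)
  ism_index <- list()
  for (cond in names(isms)) {
    for (m in isms[[cond]]) {
      f <- sprintf("ism_%s_t%03d.tsv", cond, as.integer(attr(m, "t")))
      write_ism(m, file.path(ism_dir, f))
      ism_index[[length(ism_index) + 1]] <- list(
        file = f, condition = cond, t = attr(m, "t"),
        n_samples = attr(m, "sample_count"))
    }
  }
  jsonlite::write_json(ism_index, file.path(ism_dir, "index.json"),
                       auto_unbox = TRUE, digits = NA)

  traj <- weight_trajectories(isms, config$partition,
                              modes = config$modes,
                              include_diagonal = config$include_diagonal)
  null <- circular_null(clean, seg, config$partition,
                        modes = config$modes,
                        n_realizations = config$n_realizations,
                        include_diagonal = config$include_diagonal,
                        seed = config$seed + 2L)
  res <- test_slopes(traj, null)
  write_weights(res$weights, file.path(out_dir, "weights.tsv"))
  jsonlite::write_json(
    list(slopes = res$slopes, slope_diff = res$slope_diff),
    file.path(out_dir, "slope_tests.json"), auto_unbox = TRUE, digits = NA)

  resolved <- config
  resolved$partition <- NULL
  jsonlite::write_json(
    list(config = unclass(resolved),
         partition_rois = nrow(config$partition),
         package_version = as.character(utils::packageVersion("iscnet")),
         seed = config$seed),
    file.path(out_dir, "pipeline_config.json"), auto_unbox = TRUE,
    digits = NA)
  utils::write.table(config$partition,
                     file.path(out_dir, "partition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  invisible(list(out_dir = out_dir, schedule = schedule, sim = sim,
                 labels = labels, series = clean, seg = seg, isms = isms,
                 weights = res$weights, slopes = res$slopes,
                 slope_diff = res$slope_diff, truth = gen$truth))
}
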