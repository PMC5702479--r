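# iscnet

Dynamic intersubject correlation (ISC) network analysis for paradigms in
which threat waxes and wanes continuously — two circles meander on a
screen, a shock follows if they touch, and periods of *approach* (circles
closing in) alternate with periods of *retreat*.

`iscnet` is for researchers who want to ask how the functional coupling of
large-scale brain networks (salience, executive, task-negative) and
subcortical threat regions changes with threat imminence, using
correlations computed **across brains** rather than within them. It also
ships a full synthetic stack — a paradigm simulator and a multi-subject
BOLD-like generator with known ground truth — so the entire pipeline can be
exercised, calibrated and power-tested without any real fMRI data.

## The method

For subject *s* and ROIs *i, j*, the leave-one-out intersubject matrix is

    ISM_S[i, j] = corr( y_s^(i),  mean_{s' != s} y_{s'}^(j) )

Averaging over subjects and symmetrizing with the transpose gives the group
matrix ISM_G; its diagonal (a region correlated with itself *across*
brains) is meaningful. Time-resolved matrices ISM_t are computed by
concatenating, across all approach (or retreat) segments, the sample at
within-segment time *t* — after discarding the first 5 s of every segment
for the hemodynamic delay and requiring at least 20 segments per slice.

Network weights reduce an ISM to one number per network pair,

    W(N1, N2) = (1 / (n1 n2)) * sum_{i in N1, j in N2} c_ij

restricted to positive or negative entries (within-network weights may
include the diagonal terms c_ii). Slopes of W over slice time are tested
against a circular-shift permutation null: every realization rotates each
subject's residual series by a random offset per run, breaking cross-brain
alignment while preserving autocorrelation, and re-runs the whole pipeline;
observed weights are also reported with the null mean subtracted.

## Worked example

Simulate a 3-run schedule with 20 approach and 20 retreat segments, a
"salience" network whose shared-signal coupling ramps up during approach
(+0.04/s) and down during retreat, 12 subjects, then run the pipeline:

```r
library(iscnet)

schedule  <- build_schedule(n_runs = 3, n_blocks = 4)
labels    <- synthetic_labels(schedule, rep(10, 20), rep(10, 20))
partition <- tibble::tibble(roi = paste0("r", 1:8),
                            network = rep(c("salience", "control"), each = 4))
coupling  <- coupling_spec(data.frame(n1 = "salience", n2 = "salience",
                                      base = 0.3, approach_slope = 0.04,
                                      retreat_slope = -0.04))
cfg   <- generator_config(partition, n_subjects = 12, coupling = coupling)
gen   <- generate_dataset(cfg, schedule, labels, seed = 1)
clean <- regress_out(gen$series, build_nuisance(schedule))
seg   <- build_slices(extract_segments(labels), lag_s = 5, min_samples = 20)
seg
#> <segment_index> lag 5 s, min_samples 20
#>   approach: 5 slices (t = 0..4 s, n = 20/20/20/20/20)
#>   retreat: 5 slices (t = 0..4 s, n = 20/20/20/20/20)

isms <- ism_dynamic(clean, seg)
traj <- weight_trajectories(isms, partition,
          pairs = data.frame(n1 = "salience", n2 = "salience"),
          modes = "positive")
null <- circular_null(clean, seg, partition,
          pairs = data.frame(n1 = "salience", n2 = "salience"),
          modes = "positive", n_realizations = 2000, seed = 2)
res  <- test_slopes(traj, null)
res$slopes
#> # A tibble: 2 × 7
#>   n1       n2       condition mode       slope   n_t  p_value
#>   <chr>    <chr>    <chr>     <chr>      <dbl> <int>    <dbl>
#> 1 salience salience approach  positive  0.0384     5 0.001000
#> 2 salience salience retreat   positive -0.0148     5 0.0220
res$slope_diff
#> # A tibble: 1 × 5
#>   n1       n2       mode       diff  p_value
#>   <chr>    <chr>    <chr>     <dbl>    <dbl>
#> 1 salience salience positive 0.0532 0.001000
```

The within-salience positive weight rises during approach (slope +0.038
per second, permutation p = 0.001) and falls during retreat (−0.015/s,
p = 0.022), and the approach-vs-retreat slope difference is significant —
recovering the injected coupling dynamics (the generator's ground-truth
slope in ISC units is `gen$truth$slopes$isc_slope[1]`, about 0.027/s;
the weight-level slope is slightly larger here because sampling noise and
positive-mode truncation also move with the ramp). `run_pipeline()` chains
the same stages, starting from simulated circle motion, and writes every
artifact (events, distances, labels, slice index, per-slice ISMs, weight
tables, slope tests, resolved config) to a directory.

The packaged ROI-to-network table (`default_partition()`) carries the
standard 13 salience, 12 executive and 12 task-negative cortical ROIs and
10 subcortical ROIs (bilateral central-medial/lateral amygdala, PAG,
habenula, BST).

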