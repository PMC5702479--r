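---
title: "Dynamic intersubject correlation networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic intersubject correlation networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During anxious anticipation, threat level can vary continuously: two circles
meander on a screen, a shock follows if they touch, and periods in which the
circles close in ("approach") alternate with periods in which they separate
("retreat"). The scientific question is how the functional coupling of
large-scale brain networks -- salience, executive, task-negative -- and of
subcortical threat regions changes as threat waxes and wanes.

`iscnet` implements the full analysis chain for this question using
*intersubject* correlation (ISC): instead of correlating two regions within
one brain, a region's time series in one subject is correlated with the
average time series of all *other* subjects. Signal that is not locked to
the shared stimulus -- idiosyncratic cognition, scanner drift, head motion
-- is uncorrelated across brains and is thereby suppressed. Because the two
sides of the correlation come from different brains, even the "diagonal"
correlation of a region with itself is meaningful.

## The intersubject correlation matrix

For subject $s$, ROI $i$ time series $y_s^{(i)}$ and the leave-one-out
average $y_{-s}^{(j)}$ of the other $N-1$ subjects for ROI $j$, the subject
matrix is

$$\mathrm{ISM}_S[i,j] = \mathrm{corr}\!\left(y_s^{(i)},\, y_{-s}^{(j)}\right).$$

Averaging $\mathrm{ISM}_S$ over subjects gives the group matrix
$\mathrm{ISM}_G$, which is symmetrized exactly by averaging with its
transpose. Raw correlations are averaged (intersubject correlations are
small and near-Gaussian; a Fisher-z path is available behind the `fisher`
flag of `ism_group()`). Undefined correlations (zero-variance vectors)
propagate as `NA` and are deleted pairwise at averaging, never imputed.

Time-resolved matrices $\mathrm{ISM}_t$ are obtained by a slicing scheme:
maximal contiguous approach/retreat segments are extracted from the
censored condition labels, the first 5 s of each segment are discarded to
let the hemodynamic response catch up with the condition, and for each
within-segment time $t$ the $t$-th retained TR of every sufficiently long
segment is concatenated into one sample vector. A slice is kept only if at
least 20 segments contribute (`min_samples`), the minimum we consider
stable for a correlation estimate; counts are necessarily non-increasing in
$t$.

## Network weights

With networks $N_1, N_2$ of sizes $n_1, n_2$ and group-ISM entries
$c_{ij}$,

$$W_{N_1,N_2} \;=\; \frac{1}{n_1 n_2} \sum_{i \in N_1,\, j \in N_2} c_{ij},$$

restricted to positive entries, negative entries, or all entries
(out-of-sign entries contribute zero while the denominator stays $n_1
n_2$, so the all-mode weight decomposes exactly into positive plus
negative). For within-network weights the cross-brain self-correlations
$c_{ii}$ are included by default; with the diagonal excluded the
denominator becomes $n_1 n_2 - n_1$. Both variants are computed because
published within-network weights do not always state which was used.
Negative-mode weights keep the size normalization by default; dividing by
the count of in-sign entries is available (`normalize = "count"`) but off,
since it changes the estimand. The subcortical index is the *raw sum* of
sign-restricted connections between one subcortical ROI and all
target-network ROIs, with the size-normalized equivalent attached for
comparability.

## Inference

Weight trajectories are summarized by their OLS slope on time. Because each
participant enters every leave-one-out pair, observations are not
independent and parametric tests are inappropriate; inference uses a
circular-shift permutation null: each realization rotates every subject's
z-scored residual series by an independent uniform offset, per run (shifted
data never cross run boundaries), and re-runs the slicing -> ISM -> weight
-> slope pipeline with the original slice indices (the paradigm timing is
not part of the null). Null means of the weights are generally nonzero --
slice sample counts are unequal and sign-restricted weights are biased --
so observed weights are reported together with null-mean-corrected values.
P-values are two-sided with add-one smoothing; two-sidedness is chosen
because both increases and decreases are scientifically meaningful.
No correction across network pairs is applied; p-values are raw.

Per-time confidence bands use a leave-one-subject-out jackknife on the full
nonlinear statistic (the sign-restricted group weight recomputed without
each subject), with a normal-quantile band at 90% by default. The band
construction is this package's choice; published figures of this kind do
not define theirs.

## The paradigm simulator

Circle displacement follows the momentum-smoothed random walk
$\Delta x_t = (1-c)\,\Delta x_{t-1} + c\,\mathcal N(0,1)\cdot
\text{noise\_scale}$ per coordinate, updated every 50 ms with $c = 0.2$;
at stationarity the displacement SD is $c/\sqrt{1-(1-c)^2} \cdot
\text{noise\_scale}$ and the lag-1 autocorrelation is $1-c$. Choices the
motion description leaves open are made as follows: the screen is the unit
square with *reflective* boundaries (position clamped, displacement
component sign-flipped), preserving smoothness without trapping circles;
`noise_scale` defaults to 0.015 so a circle roams an appreciable fraction
of the screen within a 60-s block; the circle radius defaults to 0.04.
Schedules follow the block structure: 6 runs of 6 blocks, 60 s of motion
preceded by 15 s of blank screen, 7 s of blank at the end of each run, TR
= 1 s -- 457 volumes per run. Collisions are contacts at center distance
$\le 2r$, collapsed per contact episode.

Under pure random motion the number of collisions is emergent, whereas the
original task delivered exactly 8 shocks per run in 4 of 6 blocks. How that
was engineered is not described anywhere we could follow, so the simulator
offers an explicit, clearly-flagged *steering* mode (a small attraction
toward the other circle until the block's collision quota is met, with a
short repulsive refractory period after each contact); the default remains
pure random motion. Per-TR distances aggregate the 50-ms samples by their
TR mean (configurable to onset-sample or minimum), the rule least sensitive
to sample-level jitter.

## Condition labeling and censoring

A TR is labeled approach if the TR-level distance decreased from the
previous TR, retreat if it increased; exact zero changes are excluded as
ties (no smoothing is applied, and whether the original analysis assigned
or dropped zero derivatives is unstated -- dropping is the conservative
choice). TRs are censored when they fall in rest periods, in the first 15 s
of a block (onset transients), within 15 s after a shock (closed-open
window), or when the distance fails the proximity gate. The censoring rules
are set unions: they commute, and relabeling labeled data is a no-op.

The proximity gate deserves a note: the source description says time points
were kept when the distance was *at least* 75% of the experiment-wide
maximum, but motivates the rule by wanting the circles *in relatively close
proximity* (attention wanes when they are far apart). The wording and the
rationale point in opposite directions. We implement the rationale --
retain TRs with distance $\le$ `cutoff_fraction` $\times$ max -- and expose
`gate = "far"` for the literal reading. The reference maximum is computed
over the whole experiment, not per block.

## The synthetic BOLD generator

Each subject's ROI series is

$$y_{s,i}(t) = \text{shared}_i(t) + \varepsilon_{s,i}(t) + \text{drift} +
\text{motion artifact} + \text{block response},$$

where the shared innovations are drawn per TR from a multivariate normal
whose cross-ROI correlation is constant at baseline and, inside an
approach/retreat segment, ramps linearly with within-segment time at the
configured slope per network pair. The ramp acts on the innovation
*correlations* only, keeping per-ROI variance constant, so downstream ISC
changes reflect coupling, not amplitude -- mirroring a connectivity (not
activation) claim. Correlation matrices are checked for positive
semi-definiteness at construction (matrices are linear in time and the PSD
cone is convex, so checking the endpoints of the time range covers it);
invalid configurations fail with the offending time and network pair, and
no silent nearest-PSD repair is performed.

Nuisance components have known form: per-run 4th-order polynomial drift,
six random-walk motion parameters with random ROI loadings (the motion
tables are stored with the dataset so preprocessing can use them), and a
block-evoked response obtained by convolving the block boxcar with a
canonical double-gamma HRF (positive lobe peaking at 6 s, undershoot at
16 s, ratio 1/6; gamma shapes are chosen so each lobe's mode sits exactly
at its nominal latency). Subject noise is white by default with an
optional AR(1) flag. The shared component is *not* HRF-convolved by
default: convolution would smear the per-TR coupling ramp on which the
ground truth is defined, while the block-evoked component exercises the
HRF path regardless.

The expected leave-one-out ISC under the generator has the closed form

$$\mathbb E[\mathrm{ISM}_{ij}] \approx \frac{v\,\rho_{ij}}
{\sqrt{v+\sigma^2}\,\sqrt{v+\sigma^2/(N-1)}},$$

with shared variance $v$, noise variance $\sigma^2$, $N$ subjects and
innovation correlation $\rho_{ij}$ ($\rho_{ii}=1$); `expected_isc()`
evaluates it. The prediction applies to residualized data, which is why
recovery tests regress nuisance terms out first.

What the generator does *not* emulate: volumetric/physiological noise
structure (cardiac, respiratory), spatial autocorrelation between ROIs,
inter-subject heterogeneity of the hemodynamic response, and non-stationary
noise. Passing tests therefore demonstrate the correctness and calibration
of the *pipeline* under its stated assumptions, not properties of any real
dataset.

## Validation studies and their sizes

Two simulation studies ship as package functions with their geometry fixed
as the study conditions:

* `calibration_study()` -- type-I error of the approach-slope test under
  the exchangeable null: datasets of pure subject-specific noise plus
  nuisance components, with no stimulus-locked signal, no coupling and in
  particular no condition-dependent coupling change. 200 datasets of 8
  subjects and 6 ROIs on a 2-run, 4-block schedule carrying 20 approach
  and 20 retreat segments of 8 TRs (slices $t = 0..2$ s with exactly the
  minimum 20 samples), 500 circular-shift realizations each.
* `recovery_study()` -- power and sign recovery when within-network
  coupling ramps up during approach and down during retreat at
  $\pm 0.025$ correlation units/s, i.e. an expected ISC change of about
  0.1 over the 6 usable seconds for 20 subjects at unit signal and noise
  variance. The ramped network has the published salience-network size
  (13 ROIs). 50 datasets on the full 6-run schedule with 54 approach and
  54 retreat segments of 12 TRs -- per-slice sample counts comparable to
  a full-size acquisition -- with 199 realizations per test.

## Numerical choices and degenerate inputs

* 0-based, half-open TR indexing in all on-disk tables; 1-based indices in
  R memory. Time in seconds is TR index times TR; slices advance in TR
  steps and are reported in seconds (they coincide at TR = 1 s).
* OLS residualization via QR; rank-deficient designs fail naming the
  collinear columns. Residuals are orthogonal to the design to $10^{-10}$
  (correlation scale) by construction.
* Z-scoring is per subject, ROI and run; zero-variance residuals stay flat
  rather than producing NaN.
* Correlations over zero-variance slices are `NA`, propagated and deleted
  pairwise, with counts recorded on the result.
* All randomness flows from explicit integer seeds; per-run/per-block
  substreams are derived with fixed multipliers so subsets are
  reproducible. Fixed seed implies bit-identical output.
* `min_samples < 2` and `cutoff_fraction` outside $(0,1]$ are rejected
  before any computation, as are permutation requests below 100
  realizations (below 1000 warns).

## Known limitations

The circular-shift null destroys the shared stimulus-locked component, so
it represents the sampling variability of *misaligned* data. The slope
test is therefore exactly calibrated only when the data are exchangeable
under circular shifts, i.e. when no shared component is present. As soon
as a stimulus-locked signal exists -- even an uncoupled one whose slope
null is true -- the null understates the variability of the aligned
weight estimates and the test becomes anti-conservative, increasingly so
as the shared signal strengthens. This is a property of the resampling
scheme itself, not of the implementation; it matters little in the
weak-synchrony regime real intersubject correlations occupy (values of a
few hundredths), but it can be probed directly through the
`shared_variance` argument of `calibration_study()`. The power study --
whose prescribed effect size mathematically requires a strong shared
component -- should accordingly be read as a benchmark of sensitivity,
not of type-I control.

Other limitations: segment labeling derives from simulated trajectories,
so segment-count statistics of any particular acquisition are not
reproduced; the jackknife band and the two-sided p-value convention are
this package's constructions; and no multiple-comparison control is
applied across network pairs, matching the original analysis style.
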