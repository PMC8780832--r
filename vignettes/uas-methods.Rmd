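---
title: "Movement analysis on the unit acceleration sphere: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement analysis on the unit acceleration sphere: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements: the
models, the tunable parameters, the numerical conventions, and the places
where the design was genuinely open and a choice had to be made.

## The problem

A waist-worn IMU sampling at 100 Hz produces some 8.6 million samples per
channel per day. Multi-day recordings of activities of daily living (ADL)
are therefore dominated — by volume — by samples that carry almost no
movement information: quiet standing, sitting, lying. The package implements
a visualization-driven route to the informative minority: every acceleration
sample is mapped to spherical coordinates, projected onto the unit
acceleration sphere (UAS), and binned by orientation; per-bin statistics of
the magnitude then separate rest-like orientations from movement-bearing
ones, and the surviving samples are cut into fixed-length windows for
sequence classification and scalar movement metrics.

## Coordinate conventions

The sensor frame has +x toward the participant's left, +y vertically up, +z
posterior; quiet upright standing reads `a = (0, -1, 0)` g. The transform is

* `rho = sqrt(ax^2 + ay^2 + az^2)` — resultant magnitude in g,
* `theta = atan2(ay, sqrt(ax^2 + az^2))` — elevation from the equatorial
  x–z plane, so standing gravity is the *south pole* (`theta = -pi/2`),
* `phi = atan2(ax, -az)` — azimuth in `[-pi, pi]`.

The azimuth convention deserves a note: the printed form of the azimuth
formula in this literature is ambiguous about the sign of the z argument. We
adopt `atan2(ax, -az)`, which maps the participant's left (+x) to
`phi = +pi/2` and makes `phi = 0` the sagittal split used by the asymmetry
index, with `atan2(ax, az)` available as a configuration switch
(`phi_convention = "pos_z"`). Both elevation and azimuth are computed with
`atan2` so they are defined everywhere except the zero vector, which is an
error; at the exact poles the azimuth is conventionally 0.

Bins are 1 degree in both angles — 360 azimuth x 180 elevation = 64,800
bins. Edges are half-open `[lo, hi)` with the top edge closed, so the bins
partition the closed angle ranges exactly; the partition property is tested
against a brute-force edge scan.

## Bin statistics and the information filter

For each bin we accumulate the count, the empirical probability
(count / total), and the mean and standard deviation of the *raw* per-sample
magnitude (no smoothing is applied first; whether any smoothing should
precede binning is not settled in the source literature, and raw magnitudes
are the least-surprising choice). The per-bin SD is the population SD
(divide by n): bins are descriptive summaries of the samples they contain,
not estimators of a superpopulation; `sd_type = "sample"` switches to n-1 if
wanted. Empty bins carry *missing* statistics, never zero — a zero SD would
make an empty bin look like a perfectly quiet rest bin and slip through the
filter below. Single-sample bins have SD 0.

Information-rich samples are selected by three conjunctive constraints:

1. **Elevation**: `theta` in `[-pi/2, -pi/3]` — a neighbourhood of the
   south pole, where upright-activity accelerations live.
2. **Daytime**: wall-clock in `[07:00, 20:00)`, half-open.
3. **Bin filter**: the sample's orientation bin must look like movement:
   SD of `|a|` at least 0.02 g *and* mean `|a|` at least 0.02 g away from
   1 g.

The combination rule inside constraint 3 is configurable (`combine_rule`).
The literal reading of the rule is the conjunction (AND), which we default
to; the stated *rationale* — excluding bins that are simultaneously
low-variability and near-gravity — corresponds to the disjunction (OR),
which is strictly more permissive. Both are implemented; the monotonicity
property (tightening any criterion never grows the selection) is tested for
both.

Selected samples are split into contiguous 3-second windows (300 timesteps
at 100 Hz), non-overlapping, taken left-to-right within each maximal
contiguous run; a run shorter than the window yields nothing, and windows
never span a timestamp gap (greater than 1.5 sample intervals) or an
unselected sample. Each timestep carries 12 channels: the raw triaxial
acceleration and angular velocity, the resultant magnitude, the three
UAS-projected components, and the two sphere angles. Twelve, not thirteen:
the reference architecture's first-layer parameter count (170,400 with 200
recurrent units) back-solves to an input dimension of exactly 12, which
settles an inconsistency in the prose description of the feature list.

## Scalar movement metrics

* **Higher-acceleration fraction (HAF)** — `log10(n_above / n_selected)`
  over the daytime + elevation selection, with `|a| > 2` g as the
  high-acceleration threshold. Always at most 0. When no sample exceeds the
  threshold the result is a sentinel, not `-Inf`. The threshold is printed
  inconsistently in the source literature (one occurrence of "-2g"); 2 g is
  used, configurably. The log base is not stated there either; base 10 is
  the default (the reported group means are plausible as base-10 magnitudes
  of modest count ratios), natural log is a switch.
* **Acceleration asymmetry index (AAI)** — among selected samples with
  `|a| > 2` g, count right-directed (`phi < 0`, `n_R`) and left-directed
  (`phi >= 0`, `n_L`); the index is `|log10(n_R / n_L)|`. The signed ratio
  and raw counts are always reported alongside, since the absolute value
  discards the side. Mirror invariance (`ax -> -ax` leaves `|AAI|`
  unchanged and swaps the counts) is a tested invariant. Counting is
  per-sample, not per-event; the alternative is not distinguishable from
  the source description.
* **Sleep detection** — per 1-second window of `R = sqrt(ax^2 + az^2)`
  (gravity lies in the x–z plane when lying), flag sleep when
  `[mean - variance, mean + variance]` fits inside `[0.97, 1.02]` g.
  Variance, not SD, enters the band test — as the rule is conventionally
  stated; with the tight noise floor of modern MEMS accelerometers the
  variance of a still second is ~1e-4 g^2, so the band test is dominated by
  the mean, and the choice is inconsequential in practice but documented.
* **Activity amplitude** — the detrended resultant acceleration
  `DRA = | |a| - 1 |` integrated (trapezoid) over each contiguous
  supra-threshold epoch. A noise floor of 0.02 g delimits epochs: with any
  real sensor the DRA never touches exact zero, so "supra-zero" needs an
  operational floor. Epochs are banded low/medium/high by their *peak* DRA
  against cut points 0.1 and 0.3 g — these cut points come from the
  wider activity-banding literature rather than a value printed in the
  source, and are fully configurable and echoed into every report — and
  credited to one of four six-hour time zones by their *starting*
  wall-clock time (assignment by start is a documented choice; epochs are
  seconds-to-minutes long, so straddling is rare).
* **Movement transitions** — peaks of the magnitude with prominence at
  least 0.2 g and separation at least 1 s, where the surrounding
  trough-to-trough span is at most 3 s. The precise transition definition
  in the cited prior work is not reproduced in the source; this detector is
  a documented approximation with every parameter exposed. Peaks are
  located on a 0.05-s moving average (sensor noise creates spurious local
  maxima at every other sample), prominence is assessed within a
  window of twice the maximum span (the neighbourhood relevant to short
  events), and statistics are computed on the raw magnitude.
* **Complex Morlet wavelet spectrogram** — convolution of the mean-removed
  magnitude with complex sinusoids under Gaussian envelopes
  (`sd = cycles / (2 pi f)`, default 7 cycles, kernels truncated at 4 SD,
  unit-energy normalised), power as squared modulus. Frequency recovery,
  DC rejection and chirp ridge tracking are tested.
* **Cohen's d** — the standard pooled-SD effect size, provided because
  group comparisons at millions of samples make p-values meaningless;
  inference beyond the effect size is left to standard tools.

## The sequence classifier

The window classifier is the stacked-LSTM architecture with the layer sizes
fixed by its published parameter table: LSTM(200, sequence output) → batch
normalization over the 200 channels → LSTM(50, last output) → dropout →
dense(50, ReLU) → dropout → dense(15, ReLU) → dense(1, sigmoid), on
300 x 12 inputs. `count_parameters()` reproduces the table analytically
(the batch-norm count of 4 per channel includes the two running statistics).

No deep-learning framework is available to R in this project's dependency
set, so the network — forward pass, backpropagation through time,
batch-norm backward, inverted dropout, Adam — is implemented from scratch in
RcppArmadillo, in single precision (the norm for neural network training).
Choices the source leaves open, all exposed as arguments with these
defaults: binary cross-entropy loss; Adam with learning rate 1e-3; batch
size 64; dropout probability 0.2; global-norm gradient clipping at 1.0
(standard practice for recurrent nets); per-channel z-scoring of the inputs
with statistics computed on the training set only (the angle channels are
standardized like the rest); batch-norm on the channel axis with batch
statistics shared across batch and time, running statistics (momentum 0.9,
epsilon 1e-3) at inference. Training draws initialization, shuffling and
dropout from one seeded Mersenne Twister stream, so a fixed seed reproduces
training bit-for-bit under single-threaded numerics.

ROC evaluation sweeps every distinct score as a threshold and integrates
trapezoidally; ties collapse to one operating point, and the area is
invariant under monotone transforms of the scores (tested, and cross-checked
against an independent ROC implementation). A helper returns the smallest
threshold achieving a requested sensitivity — the operating point a
screening application would pick.

The 80/20 train/validation split shuffles windows, not subjects; a
subject-level split would be the stricter design, but sample-level splitting
is what the reference protocol describes, and the limitation (validation
windows share subjects with training windows) is inherited knowingly.

## The synthetic generator

Real multi-day recordings of the target population are not redistributable,
so the package carries a seeded generator (`profile_config()`,
`generate_recording()`, `generate_cohort()`) whose output exercises every
pipeline stage. It emulates: upright rest (gravity along -y plus 0.01 g
noise), supine sleep in configurable wall-clock windows (gravity along -z,
satisfying the sleep band by construction), gait bouts, and sporadic brief
spikes exceeding 2 g with a configurable left/right bias
(`P(right) = f / (1 + f)` for asymmetry factor `f`) — the stroke-like
profile combines `asymmetry_factor = 3`, global amplitude scale 0.6, a
reduced spike rate, and hemiparetic gait: step frequency 1.1 Hz versus the
healthy 1.8 Hz, larger bout-to-bout cadence variability (SD 0.25 vs
0.15 Hz — within-subject cadence is quite stable in healthy walkers), and
step-to-step amplitude alternation (`gait_limp = 0.35`, the classic
strong-step / weak-step limp, which puts a subharmonic into the stroke
waveform). All three are well-documented phenomenology of post-stroke
movement.

Gait is deliberately *not* a biomechanical simulation. A bout is magnitude
loading along a quasi-fixed tilted axis: the trunk leans 6–12 degrees off
vertical in a random azimuth, the magnitude oscillates at the step frequency
(plus a first harmonic and stride-to-stride gain jitter) around a mean
raised above 1 g by impact loading, and the orientation wobbles inside a
bounded cone independently of the magnitude phase. That last independence is
the load-bearing design decision: on real wearables, soft-tissue wobble and
impact jitter decorrelate the orientation bin a sample lands in from the
instantaneous magnitude, and it is exactly this decorrelation that makes
gait bins pass the mean-deviation filter as whole contiguous stretches. An
earlier sinusoid-superposition design tied elevation deterministically to
magnitude, which made every bin where the implied magnitude crossed 1 g fail
the filter and shredded the selection mask into sub-window fragments — a
useful reminder that the filter tests *bins*, not samples.

Default daily structure: sleep 23:00–07:00; gait bouts at rates
(0.2, 10, 10, 5) per hour across the four six-hour zones, mean duration
60 s, band mix 0.3/0.5/0.2 (low/medium/high, peak DRA targets 0.06 / 0.18 /
0.5 g); >2 g spikes at 30 per daytime hour, 0.2 s long, peak factor
2.4 ± 0.1 g. The spike rate is set so that a day-scale recording contains
several hundred high-acceleration events: the asymmetry index is a log
count ratio, whose sampling noise scales as `1 / sqrt(events)`, and a
symmetric mover should measure near zero at realistic event counts — about
one brief vigorous movement every two minutes of active daytime. Low-band
bouts mostly fail the information filter (their mean deviation sits under
0.02 g); that is intended — weak movement is exactly what the filter is for.

What the generator does **not** emulate: real gait waveform morphology
(heel-strike transients, double-support timing), gyroscope physiology
(gyro channels are plumbing-grade noise plus bout-locked oscillation),
off-body wear periods, posture diversity beyond upright/supine, and
device-specific artefacts. Consequently, passing tests demonstrate that the
pipeline's machinery is correct and its statistics behave as designed on
signals with the stated structure — they do not certify clinical
performance on real cohorts, whose published headline numbers (accuracy,
AUC, group means) require the original recordings.

## Problem sizes used by the test suite and acceptance script

Simulations are scaled to desk hardware as the package's own choice of
study size: bin-statistics oracles run on 1e5-sample recordings; asymmetry
calibration uses ten seeds per condition on 13-hour daytime recordings
(about 390 spikes each, where the symmetric profile measures
`|AAI| < 0.05`); sleep and transition recovery use day-scale and
minute-scale plants respectively; the classifier check trains the full
reference architecture for 8 epochs (learning-rate step decay for the final
third) on a 2,000-window cohort drawn from six simulated subjects, five
seeds, which reliably clears ROC area 0.9 (observed seed means ~0.94) while
a label-shuffled control stays at chance. One full 3-day recording
(25.92 million samples per channel) is generated once to verify
sample-count bookkeeping.

## Known limitations

* The AND/OR ambiguity in the bin filter is resolved by configuration, not
  evidence; results under the two rules differ in selection volume.
* Per-sample (not per-event) counting makes HAF and AAI sensitive to the
  sampling rate around threshold crossings.
* The transition detector approximates an under-specified definition.
* The classifier's determinism guarantee holds for single-threaded BLAS;
  multi-threaded gemm may reorder floating-point sums.
* Sample-level splitting overstates generalization to unseen subjects.
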