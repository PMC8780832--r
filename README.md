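# adlsphere

Visualization-driven analysis of multi-day waist-worn accelerometry for
human movement research, with an emphasis on post-stroke movement asymmetry.

A waist-worn IMU sampling at 100 Hz yields more than 8.6 million samples per
channel per day, most of them rest. `adlsphere` implements a pipeline that
finds the informative minority and quantifies stroke-relevant movement
characteristics:

* **Unit acceleration sphere (UAS).** Every acceleration sample
  `a = (ax, ay, az)` (units of g) is mapped to spherical coordinates
  `rho = |a|`, elevation `theta = atan2(ay, sqrt(ax^2 + az^2))` (upright
  standing is the south pole, `theta = -pi/2`), azimuth
  `phi = atan2(ax, -az)`, and projected onto the unit sphere (`rho = 1`).
  A 360 x 180 grid of one-degree orientation bins accumulates the count,
  probability, mean and SD of `|a|` per bin; polar hemisphere views render
  these fields as the familiar pole-centred maps.
* **Information-rich window extraction.** Samples are kept when
  `theta <= -pi/3`, the wall clock is in [07:00, 20:00), and the sample's
  bin looks like movement (`sd(|a|) >= 0.02` g and `|mean(|a|) - 1| > 0.02`
  g). Contiguous selected runs are cut into non-overlapping 3-s windows of
  300 timesteps x 12 channels (raw accel + gyro, `|a|`, UAS components,
  `theta`, `phi`).
* **Movement metrics.** Higher-acceleration fraction
  `HAF = log10(n_{|a|>2g} / n_selected)`; acceleration asymmetry index
  `AAI = |log10(n_R / n_L)|` over high-acceleration samples right
  (`phi < 0`) vs left (`phi >= 0`) of the sagittal plane; actigraphic sleep
  detection (1-s windows of `sqrt(ax^2 + az^2)` inside [0.97, 1.02] g);
  banded activity amplitudes (time integral of `||a| - 1|` per epoch, by
  intensity band and six-hour time zone); movement-transition statistics;
  complex Morlet wavelet spectrograms; Cohen's d.
* **Sequence classifier.** A stacked LSTM
  (200 seq -> batchnorm -> 50 -> dropout -> 50 ReLU -> dropout -> 15 ReLU
  -> 1 sigmoid) for healthy-vs-stroke window classification, implemented
  from scratch in RcppArmadillo (BPTT, Adam, gradient clipping,
  seed-reproducible), with an analytic per-layer parameter counter and ROC
  evaluation.
* **Synthetic generator.** Seeded multi-day recordings with healthy-like
  and stroke-like profiles (sleep windows, gait bouts, >2 g spikes with a
  configurable left/right bias, amplitude reduction, hemiparetic cadence)
  so the whole pipeline is testable without clinical data.

## Worked example

```r
library(adlsphere)

# a 6-hour daytime recording of a healthy-profile wearer, and a stroke-like one
rec  <- generate_recording(profile_config(days = 6/24, seed = 6,
                                          start_clock = "2021-06-07 08:00:00"))
recS <- generate_recording(stroke_profile(days = 6/24, seed = 11,
                                          start_clock = "2021-06-07 08:00:00"))

grid <- compute_bin_grid(rec)
grid
#> <bin_grid> 360 x 180 one-degree bins; 2160000 samples in 5187 occupied bins
#>   max bin probability: 0.001994

plot(hemisphere_view(grid, "south", "prob", log_scale = TRUE))

ws <- extract_windows(rec)
ws
#> <window_set> 534 windows of 300 timesteps x 12 channels

movement_metrics(rec)
#> <metric_report>
#>   HAF: -2.9170  (2615 / 2160000 samples > 2 g)
#>   AAI: 0.0262  (right 1347 / left 1268)
#>   sleep: 0.00 h;  transitions: 991
#>   activity amplitude (g.s): low 27.2, medium 99, high 148
movement_metrics(recS)$aai     # right-biased spikes: |log10 ratio| well above 0
#> [1] 0.4125805
```

The healthy profile measures an asymmetry index near zero (balanced left and
right high-acceleration counts — single six-hour recordings scatter around
zero with an SD near 0.1, so individual draws up to ~0.2 are unremarkable),
while the stroke profile's index sits near `log10(3) ~ 0.48`, its planted
right:left bias. HAF near -2.9 says roughly one selected sample in 800
exceeds 2 g over this active afternoon.

Classifier:

```r
cnt <- count_parameters(network_spec())
cnt
#>       lstm_1   batch_norm       lstm_2    dropout_1 dense_relu_1
#>       170400          800        50200            0         2550
#>    dropout_2 dense_relu_2 dense_sigmoid
#>            0          765           16

sp  <- split_train_val(bind_window_sets(list(ws, extract_windows(recS))), 0.8, seed = 1)
fit <- fit_lstm(sp$train, epochs = 3, seed = 1, validation = sp$val)
evaluate_roc(fit, windows = sp$val)
```

A command-line wrapper over the same functions ships in `inst/cli/adlsphere`
(verbs: `synth`, `visualize`, `extract`, `metrics`, `train`, `eval`).

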