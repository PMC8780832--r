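# daytime criteria that keep the whole of a midday fixture selected
crit_all_day <- selection_criteria()

test_that("higher-acceleration fraction follows the log10 count ratio", {
  # 1000 upright samples, 10 of them boosted above 2 g -> log10(0.01) = -2
  accel <- matrix(rep(c(0, -1, 0), 1000), ncol = 3, byrow = TRUE)
  accel[1:10, 2] <- -2.5
  rec <- make_rec(accel)
  h <- higher_acceleration_fraction(rec, crit_all_day)
  expect_equal(h$haf, -2)
  expect_equal(h$n_above, 10L)
  # all samples above threshold -> log(1) = 0
  rec_hi <- const_rec(c(0, -3, 0), 50)
  expect_equal(higher_acceleration_fraction(rec_hi, crit_all_day)$haf, 0)
  # none above -> sentinel, never -Inf
  rec_lo <- const_rec(c(0, -1, 0), 50)
  h0 <- higher_acceleration_fraction(rec_lo, crit_all_day)
  expect_true(is.na(h0$haf))
  expect_equal(h0$sentinel, "none-above-threshold")
  # empty selection (night recording) errors
  rec_n <- const_rec(c(0, -1, 0), 50, start = "2021-06-07 03:00:00")
  expect_error(higher_acceleration_fraction(rec_n, crit_all_day), "no samples")
  # HAF <= 0 always on generated recordings
  for (s in 1:3) {
    h <- higher_acceleration_fraction(generate_recording(day_cfg(s, hours = 1)),
                                      crit_all_day)
    expect_lte(h$haf, 0)
  }
})

test_that("asymmetry index is the absolute log10 side ratio", {
  # construct high-acceleration samples at theta < -pi/3 with known sides:
  # right means phi < 0, i.e. ax < 0 under the atan2(ax, -az) convention
  side_sample <- function(side) c(side * 0.8, -2.5, 0.05)
  accel <- rbind(
    matrix(rep(side_sample(-1), 200), ncol = 3, byrow = TRUE),
    matrix(rep(side_sample(+1), 100), ncol = 3, byrow = TRUE))
  rec <- make_rec(accel)
  a <- acceleration_asymmetry_index(rec, crit_all_day)
  expect_equal(a$n_right, 200L)
  expect_equal(a$n_left, 100L)
  expect_equal(a$aai, log10(2), tolerance = 1e-12)
  expect_equal(a$aai_signed, log10(2), tolerance = 1e-12)
  # balanced sides -> 0
  b <- acceleration_asymmetry_index(
    make_rec(rbind(accel[1:100, ], accel[201:300, ])), crit_all_day)
  expect_equal(b$aai, 0)
  # one-sided counts -> sentinel
  o <- acceleration_asymmetry_index(make_rec(accel[1:50, ]), crit_all_day)
  expect_true(is.na(o$aai))
  expect_equal(o$sentinel, "one-sided-counts")
})

test_that("mirroring a recording leaves |AAI| unchanged and flips its sign", {
  rec <- generate_recording(day_cfg(3, hours = 2,
                                    asymmetry_factor = 2))
  m <- rec
  m$accel[, 1] <- -m$accel[, 1]
  a1 <- acceleration_asymmetry_index(rec, crit_all_day)
  a2 <- acceleration_asymmetry_index(m, crit_all_day)
  expect_equal(a1$aai, a2$aai)
  expect_equal(a1$aai_signed, -a2$aai_signed)
  expect_equal(a1$n_right, a2$n_left)
})

test_that("sleep rule follows the x-z plane magnitude band", {
  # supine stillness: gravity along -z -> R_xz = 1, flagged
  sup <- const_rec(c(0, 0, -1), 500)
  s <- detect_sleep(sup)
  expect_true(all(s$window_flags))
  expect_equal(s$sleep_hours, 5 / 3600)
  # upright standing: R_xz = 0, never flagged
  up <- detect_sleep(const_rec(c(0, -1, 0), 500))
  expect_false(any(up$window_flags))
  expect_equal(up$sleep_hours, 0)
  # boundary arithmetic: mean +/- variance must fit inside [0.97, 1.02]
  edge <- detect_sleep(const_rec(c(0, 0, -0.96), 200))
  expect_false(any(edge$window_flags))
})

test_that("planted supine epochs are recovered within 1 percent", {
  # 2 h sleep planted in an 8 h recording
  cfg <- profile_config(days = 8 / 24, start_clock = "2021-06-07 06:00:00",
                        sleep_windows = list(c(8, 10)), seed = 12)
  rec <- generate_recording(cfg)
  s <- detect_sleep(rec)
  expect_lt(abs(s$sleep_hours - 2) / 2, 0.01)
  # additivity over disjoint epochs
  cfg2 <- profile_config(days = 8 / 24, start_clock = "2021-06-07 06:00:00",
                         sleep_windows = list(c(8, 9), c(11, 12)), seed = 12)
  s2 <- detect_sleep(generate_recording(cfg2))
  expect_lt(abs(s2$sleep_hours - 2) / 2, 0.01)
})

test_that("activity amplitude integrates detrended magnitude by band and zone", {
  # constant 1 g: no activity at all
  flat <- activity_amplitude(const_rec(c(0, -1, 0), 1000, fs = 100))
  expect_equal(flat$total, 0)
  expect_equal(unname(flat$by_band), c(0, 0, 0))
  # sustained |a| = 1.2 for 10 s: DRA 0.2, integral 2.0 g.s, medium band
  sus <- activity_amplitude(const_rec(c(0, -1.2, 0), 1000, fs = 100))
  expect_equal(sus$total, 2, tolerance = 0.01)
  expect_equal(unname(sus$by_band["medium"]), sus$total)
  # peak above the upper cut lands in the high band
  hi <- activity_amplitude(const_rec(c(0, -1.5, 0), 1000, fs = 100))
  expect_equal(unname(hi$by_band["high"]), hi$total)
  # epoch starting 03:00 is credited to time zone 1
  z <- activity_amplitude(const_rec(c(0, -1.2, 0), 1000, fs = 100,
                                    start = "2021-06-07 03:00:00"))
  expect_equal(unname(z$by_timezone[["zone1"]]), z$total)
  expect_error(activity_amplitude(const_rec(c(0, -1, 0), 10),
                                  band_thresholds = c(0.3, 0.1)), "increasing")
})

test_that("band totals never grow when their lower cut point rises", {
  rec <- generate_recording(day_cfg(4, hours = 1))
  a1 <- activity_amplitude(rec, c(0.1, 0.3))
  # medium's lower cut is the first threshold, high's is the second
  a2 <- activity_amplitude(rec, c(0.15, 0.3))
  expect_lte(a2$by_band[["medium"]], a1$by_band[["medium"]] + 1e-9)
  a3 <- activity_amplitude(rec, c(0.1, 0.4))
  expect_lte(a3$by_band[["high"]], a1$by_band[["high"]] + 1e-9)
  # totals are conserved across banding choices
  expect_equal(a2$total, a1$total)
})

test_that("activity amplitude is rotation invariant", {
  set.seed(71)
  accel <- matrix(rnorm(3000, sd = 0.5), ncol = 3)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  a1 <- activity_amplitude(make_rec(accel))
  a2 <- activity_amplitude(make_rec(accel %*% q))
  expect_equal(a1$total, a2$total, tolerance = 1e-9)
})

test_that("transition detection recovers planted pulse trains exactly", {
  fs <- 100
  baseline <- function(n) matrix(rep(c(0, -1, 0), n), ncol = 3, byrow = TRUE)
  # flat signal: none
  expect_equal(detect_transitions(make_rec(baseline(2000)))$n_transitions, 0)
  # single 1.5 g, 2 s raised-cosine bump
  n <- 3000
  acc <- baseline(n)
  tt <- seq(0, 2, length.out = 200)
  acc[1401:1600, 2] <- -(1 + 0.5 * sin(pi * tt / 2)^2)
  tr <- detect_transitions(make_rec(acc, fs = fs))
  expect_equal(tr$n_transitions, 1)
  expect_equal(tr$transitions$max, 1.5, tolerance = 0.01)
  expect_equal(tr$transitions$range, 0.5, tolerance = 0.01)
  expect_lt(tr$transitions$duration_s, 3)
  # k pulses, 5 s apart, k = 1..10 (parameterised planted-event recovery)
  for (k in c(1, 3, 7, 10)) {
    n <- (k + 1) * 500 + 500
    acc <- baseline(n)
    for (j in seq_len(k)) {
      i0 <- 500 * j
      acc[i0:(i0 + 149), 2] <- -(1 + 0.6 * sin(pi * seq(0, 1.49, 0.01) / 1.5)^2)
    }
    expect_equal(detect_transitions(make_rec(acc, fs = fs))$n_transitions, k)
  }
})

test_that("morlet spectrogram recovers tones, rejects DC, tracks chirps", {
  fs <- 100
  t <- (0:2999) / fs
  freqs <- seq(0.5, 6, by = 0.25)
  # pure 2 Hz tone: power argmax at 2 Hz (away from edges)
  x <- 1 + 0.3 * sin(2 * pi * 2 * t)
  sp <- cmw_spectrogram(signal = x, freqs = freqs, sample_rate_hz = fs)
  mid <- 1000:2000
  peak_f <- freqs[apply(sp$power[mid, ], 1, which.max)]
  expect_equal(median(peak_f), 2)
  # DC signal: negligible power everywhere
  spd <- cmw_spectrogram(signal = rep(1, 3000), freqs = freqs,
                         sample_rate_hz = fs)
  expect_lt(max(spd$power), 1e-20)
  # chirp 0.5 -> 5 Hz: ridge increases monotonically in time
  f_inst <- seq(0.5, 5, length.out = 6000)
  phase <- 2 * pi * cumsum(f_inst) / fs
  xc <- sin(phase)
  spc <- cmw_spectrogram(signal = xc, freqs = freqs, sample_rate_hz = fs)
  sel <- seq(1500, 4500, by = 500)
  ridge <- freqs[apply(spc$power[sel, ], 1, which.max)]
  expect_true(all(diff(ridge) >= 0))
  expect_gt(tail(ridge, 1), head(ridge, 1))
  # contract errors
  expect_error(cmw_spectrogram(signal = x, freqs = 60, sample_rate_hz = fs),
               "rate/2")
  expect_error(cmw_spectrogram(signal = x[1:50], freqs = 0.5,
                               sample_rate_hz = fs), "longer")
})

test_that("cohens_d matches its definition and recovers planted effects", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # means 1 and 0 with common SD 1 (exact sample construction)
  a <- c(0, 2); b <- c(-1, 1)
  expect_equal(cohens_d(a, b), 1 / sqrt(2))  # pooled sd = sqrt(2) here
  expect_true(is.na(cohens_d(c(1, 1), c(1, 1))))
  set.seed(81)
  x <- rnorm(1e5, 0.28); y <- rnorm(1e5, 0)
  expect_equal(cohens_d(x, y), 0.28, tolerance = 0.01)
})

test_that("metric report aggregates and serializes", {
  rec <- generate_recording(day_cfg(5, hours = 1))
  m <- movement_metrics(rec)
  expect_s3_class(m, "metric_report")
  expect_equal(m$n_left + m$n_right, m$haf_counts$n_above)
  df <- as.data.frame(m)
  expect_equal(nrow(df), 1)
  f <- tempfile(fileext = ".json")
  write_metric_report(m, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$sleep_hours, m$sleep_hours)
  expect_equal(back$n_transitions, m$n_transitions)
  unlink(f)
})
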