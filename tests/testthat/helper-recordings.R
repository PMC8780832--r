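# Small in-code fixtures used across the suite.

# recording from explicit accel rows at a given rate
make_rec <- function(accel, fs = 100, start = "2021-06-07 12:00:00",
                     gyro = NULL, group = NULL) {
  n <- nrow(accel)
  imu_recording((seq_len(n) - 1) / fs, accel, gyro, sample_rate_hz = fs,
                start_clock = start,
                subject_meta = if (is.null(group)) list() else list(group = group))
}

# constant-posture recording: n samples of a single acceleration vector
const_rec <- function(a, n, fs = 100, start = "2021-06-07 12:00:00") {
  make_rec(matrix(a, n, 3, byrow = TRUE), fs = fs, start = start)
}

# quick daytime short-recording generator config (starts mid-morning so the
# whole recording is inside the daytime window)
day_cfg <- function(seed, hours = 6, ...) {
  profile_config(days = hours / 24, start_clock = "2021-06-07 08:00:00",
                 seed = seed, ...)
}

# brute-force per-sample bin statistics accumulation (independent oracle for
# compute_bin_grid): plain loops, no shared code with the implementation
naive_bin_stats <- function(accel) {
  counts <- matrix(0L, 360, 180)
  sums <- matrix(0, 360, 180)
  sq <- matrix(0, 360, 180)
  for (k in seq_len(nrow(accel))) {
    ax <- accel[k, 1]; ay <- accel[k, 2]; az <- accel[k, 3]
    r <- sqrt(ax^2 + ay^2 + az^2)
    th <- atan2(ay, sqrt(ax^2 + az^2))
    ph <- if (ax == 0 && az == 0) 0 else atan2(ax, -az)
    i <- min(360L, as.integer(floor((ph + pi) * 180 / pi)) + 1L)
    j <- min(180L, as.integer(floor((th + pi / 2) * 180 / pi)) + 1L)
    counts[i, j] <- counts[i, j] + 1L
    sums[i, j] <- sums[i, j] + r
    sq[i, j] <- sq[i, j] + r^2
  }
  mean_a <- ifelse(counts > 0, sums / pmax(counts, 1), NA_real_)
  v <- sq / pmax(counts, 1) - mean_a^2
  v[!is.na(v) & v < 0] <- 0
  sd_a <- sqrt(v)
  sd_a[counts == 0] <- NA_real_
  list(counts = counts, mean_a = mean_a, sd_a = sd_a)
}
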