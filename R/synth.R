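#' Configuration of the synthetic ADL recording generator
#'
#' Describes one simulated wearer of a waist-mounted 100 Hz IMU over one or
#' more days. The simulated day is piecewise: upright rest (gravity along
#' -y) outside the sleep windows, supine sleep (gravity in the x-z plane,
#' here along -z) inside them, periodic gait bouts during the day modelled
#' as amplitude-modulated sinusoids with harmonics superposed on gravity,
#' and sporadic brief spikes exceeding 2 g whose lateral direction carries a
#' configurable left/right bias. Stroke-like profiles use an asymmetry
#' factor above 1, a global amplitude reduction below 1 and a reduced spike
#' rate.
#'
#' @param days recording length in days (fractional allowed).
#' @param sample_rate_hz sampling rate (default 100).
#' @param start_clock wall-clock of sample 0 (defaults to midnight).
#' @param sleep_windows list of `c(start_hour, end_hour)` pairs within
#'   `[0, 24]`, non-overlapping (default 00–07 and 23–24, i.e. sleep
#'   23:00–07:00).
#' @param gait_bout_rate_per_hour expected gait bouts per hour in each of
#'   the four six-hour time zones (midnight-anchored).
#' @param bout_duration_s mean gait-bout duration in seconds.
#' @param gait_freq_hz,gait_freq_jitter step-cycle frequency mean and SD.
#' @param bout_amp_weights mixture weights of low/medium/high-amplitude
#'   bouts (sum to 1).
#' @param asymmetry_factor ratio of right- to left-directed high-acceleration
#'   spikes; 1 = symmetric, values above 1 bias spikes to the right
#'   (`phi < 0`).
#' @param gait_limp step-to-step amplitude alternation fraction (0 = even
#'   steps; hemiparetic gait alternates strong and weak steps).
#' @param amp_scale global movement-amplitude multiplier (stroke < 1).
#' @param high_g_event_rate expected spikes exceeding 2 g per daytime hour
#'   (07:00–20:00).
#' @param noise_sd_g white accelerometer noise SD in g (default 0.01).
#' @param seed integer seed; the generated byte stream is a pure function of
#'   the configuration.
#' @param group subject label stored in the recording metadata.
#' @return An object of class `profile_config`.
#' @export
profile_config <- function(days = 3, sample_rate_hz = 100,
                           start_clock = as.POSIXct("2021-06-07 00:00:00", tz = "UTC"),
                           sleep_windows = list(c(0, 7), c(23, 24)),
                           gait_bout_rate_per_hour = c(0.2, 10, 10, 5),
                           bout_duration_s = 60,
                           gait_freq_hz = 1.8, gait_freq_jitter = 0.15,
                           bout_amp_weights = c(low = 0.3, medium = 0.5, high = 0.2),
                           asymmetry_factor = 1, gait_limp = 0, amp_scale = 1,
                           high_g_event_rate = 30, noise_sd_g = 0.01,
                           seed = 1L, group = "healthy") {
  stopifnot(days > 0, sample_rate_hz > 0, asymmetry_factor >= 1,
            gait_limp >= 0, gait_limp < 1,
            amp_scale > 0, high_g_event_rate >= 0, noise_sd_g >= 0,
            all(gait_bout_rate_per_hour >= 0),
            abs(sum(bout_amp_weights) - 1) < 1e-9)
  sw <- lapply(sleep_windows, function(w) {
    stopifnot(length(w) == 2, w[1] < w[2], w[1] >= 0, w[2] <= 24)
    w
  })
  if (length(sw) > 1) {
    m <- do.call(rbind, sw)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-1, 1] < m[-nrow(m), 2]))
      stop("sleep windows overlap", call. = FALSE)
  }
  if (is.character(start_clock))
    start_clock <- as.POSIXct(start_clock, tz = "UTC")
  structure(list(days = days, sample_rate_hz = sample_rate_hz,
                 start_clock = start_clock, sleep_windows = sw,
                 gait_bout_rate_per_hour = rep_len(gait_bout_rate_per_hour, 4),
                 bout_duration_s = bout_duration_s,
                 gait_freq_hz = gait_freq_hz,
                 gait_freq_jitter = gait_freq_jitter,
                 bout_amp_weights = bout_amp_weights,
                 asymmetry_factor = asymmetry_factor, gait_limp = gait_limp,
                 amp_scale = amp_scale,
                 high_g_event_rate = high_g_event_rate,
                 noise_sd_g = noise_sd_g, seed = as.integer(seed),
                 group = group),
            class = "profile_config")
}

#' Stroke-like generator profile
#'
#' The healthy defaults of [profile_config()] with the stroke phenomenology
#' applied: right-biased high-acceleration spikes (`asymmetry_factor` 3),
#' globally reduced movement amplitudes (`amp_scale` 0.6), one third the
#' spike rate, and hemiparetic gait timing (reduced step cadence with larger
#' stride-to-stride variability).
#'
#' @param ... overrides passed to [profile_config()].
#' @export
stroke_profile <- function(...) {
  args <- list(...)
  defaults <- list(asymmetry_factor = 3, gait_limp = 0.35, amp_scale = 0.6,
                   high_g_event_rate = 10, gait_freq_hz = 1.1,
                   gait_freq_jitter = 0.25, group = "stroke")
  do.call(profile_config, utils::modifyList(defaults, args))
}

#' @export
print.profile_config <- function(x, ...) {
  cat("<profile_config>", x$group, "-", x$days, "day(s) at",
      x$sample_rate_hz, "Hz\n")
  cat(sprintf("  asymmetry %.2g, amp scale %.2g, >2g spikes %.3g/h\n",
              x$asymmetry_factor, x$amp_scale, x$high_g_event_rate))
  invisible(x)
}

# peak detrended-magnitude targets per bout intensity band; the sinusoid +
# harmonics waveform peaks at ~2.1x its base amplitude
.band_peak_dra <- c(low = 0.06, medium = 0.18, high = 0.5)

#' Generate one synthetic IMU recording
#'
#' Deterministic for a fixed configuration: identical config (including
#' seed) yields an identical byte stream. See [profile_config()] for the
#' signal model.
#'
#' @param cfg a [profile_config()].
#' @return An [imu_recording()] with `subject_meta$group` set from the
#'   config.
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "profile_config"))
  fs <- cfg$sample_rate_hz
  n <- round(cfg$days * 86400 * fs)
  with_seed(cfg$seed, {
    time <- (0:(n - 1)) / fs
    lt <- as.POSIXlt(cfg$start_clock)
    anchor <- lt$hour * 3600 + lt$min * 60 + lt$sec
    tod <- (anchor + time) %% 86400
    sleep <- rep(FALSE, n)
    for (w in cfg$sleep_windows)
      sleep <- sleep | (tod >= w[1] * 3600 & tod < w[2] * 3600)
    accel <- matrix(0, n, 3)
    accel[, 2] <- -1  # upright rest baseline
    gyro <- matrix(0, n, 3)

    # --- gait bouts, drawn per day and six-hour time zone -------------------
    day_of <- floor((anchor + time[c(1, n)]) / 86400)
    total_end <- anchor + time[n]
    bout_starts <- numeric(0)
    for (d in day_of[1]:day_of[2]) for (z in 1:4) {
      z0 <- d * 86400 + (z - 1) * 21600
      nb <- rpois(1, cfg$gait_bout_rate_per_hour[z] * 6)
      if (nb > 0) bout_starts <- c(bout_starts, z0 + runif(nb) * 21600)
    }
    bout_starts <- sort(bout_starts[bout_starts >= anchor &
                                      bout_starts < total_end]) - anchor
    bands <- names(cfg$bout_amp_weights)
    for (b0 in bout_starts) {
      dur <- max(10, rnorm(1, cfg$bout_duration_s, cfg$bout_duration_s / 4))
      band <- sample(bands, 1, prob = cfg$bout_amp_weights)
      A <- cfg$amp_scale * .band_peak_dra[[band]] / 2.1 * runif(1, 0.85, 1.15)
      f <- max(0.5, rnorm(1, cfg$gait_freq_hz, cfg$gait_freq_jitter))
      i0 <- floor(b0 * fs) + 1L
      i1 <- min(n, i0 + round(dur * fs) - 1L)
      if (i1 <= i0) next
      i <- i0:i1
      tau <- (i - i0) / fs
      ramp <- pmin(1, tau / 2, (dur - tau) / 2)
      ramp[ramp < 0] <- 0
      ph <- runif(1, 0, 2 * pi)
      # Gait is modelled as magnitude loading along a quasi-fixed tilted
      # longitudinal axis: the trunk leans 6-12 degrees off vertical in a
      # random azimuth for the duration of the bout, the acceleration
      # magnitude oscillates at the step frequency around a raised mean
      # (impact loading keeps mean |a| above 1 g), and the sensor orientation
      # wobbles within a bounded cone independently of the magnitude phase
      # (soft-tissue wobble). Orientation and magnitude are thus independent,
      # so every orientation bin visited during a bout sees the bout's full
      # magnitude distribution - elevated mean and wide spread - which is
      # what makes gait bins information-rich.
      eps <- runif(1, 6, 12) * pi / 180
      psi <- runif(1, 0, 2 * pi)
      dir <- c(sin(eps) * cos(psi), -cos(eps), sin(eps) * sin(psi))
      # step-to-step gain variability, piecewise constant per step cycle;
      # hemiparetic limp alternates strong (sound) and weak (paretic) steps
      nstep <- ceiling(dur * f) + 1L
      gain <- pmax(0.4, rnorm(nstep, 1, 0.25)) *
        (1 + cfg$gait_limp * (-1)^(seq_len(nstep)))
      gain_t <- gain[floor(tau * f) + 1L]
      dev <- A * ramp * gain_t * (0.7 + sin(2 * pi * f * tau) +
                                    0.4 * sin(4 * pi * f * tau + ph))
      up <- matrix(c(0, -1, 0), length(i), 3, byrow = TRUE)
      dm <- up * (1 - ramp) + matrix(dir, length(i), 3, byrow = TRUE) * ramp +
        matrix(runif(3 * length(i), -0.04, 0.04), ncol = 3) * ramp
      dm <- dm / sqrt(rowSums(dm^2))
      accel[i, ] <- dm * (1 + dev)
      # trunk angular velocity during gait reaches tens of deg/s; bout-locked
      # oscillation at the step frequency, amplitude tracking the bout band
      gyro[i, 1] <- gyro[i, 1] + 300 * A * ramp * gain_t * sin(2 * pi * f * tau)
      gyro[i, 3] <- gyro[i, 3] + 180 * A * ramp * cos(2 * pi * f * tau + ph)
    }

    # --- sporadic >2 g spikes with lateral left/right bias ------------------
    day_s <- tod >= 7 * 3600 & tod < 20 * 3600 & !sleep
    n_day <- sum(day_s)
    if (n_day > 0 && cfg$high_g_event_rate > 0) {
      hours_day <- n_day / fs / 3600
      nev <- min(rpois(1, cfg$high_g_event_rate * hours_day), n_day)
      if (nev > 0) {
        day_idx <- which(day_s)
        centers <- sort(sample(day_idx, nev))
        p_right <- cfg$asymmetry_factor / (1 + cfg$asymmetry_factor)
        sides <- ifelse(runif(nev) < p_right, -1, 1)  # -1: right (phi < 0)
        half <- round(0.1 * fs)
        for (k in seq_len(nev)) {
          i <- max(1, centers[k] - half):min(n, centers[k] + half)
          env <- sin(pi * seq_along(i) / length(i))
          p <- cfg$amp_scale * max(2.0, rnorm(1, 2.4, 0.1))
          accel[i, 1] <- accel[i, 1] + 0.38 * sides[k] * p * env
          accel[i, 2] <- accel[i, 2] - 0.92 * p * env
          accel[i, 3] <- accel[i, 3] + 0.06 * p * env
          gyro[i, 2] <- gyro[i, 2] + 60 * sides[k] * env
        }
      }
    }

    # --- supine sleep overwrites any overlapping activity -------------------
    accel[sleep, 1] <- 0
    accel[sleep, 2] <- 0
    accel[sleep, 3] <- -1
    gyro[sleep, ] <- 0

    accel <- accel + matrix(rnorm(3 * n, 0, cfg$noise_sd_g), n, 3)
    sm <- as.numeric(stats::filter(rnorm(n, 0, 4), rep(0.2, 5), sides = 2))
    sm[is.na(sm)] <- 0
    gyro <- gyro + cbind(sm, sm[c(2:n, 1)], rnorm(n, 0, 2))

    imu_recording(time, accel, gyro, sample_rate_hz = fs,
                  start_clock = cfg$start_clock,
                  subject_meta = list(group = cfg$group, seed = cfg$seed))
  })
}

#' Generate a labelled synthetic cohort
#'
#' Draws per-subject jittered configurations around a healthy and a
#' stroke-like base profile, samples BMI from group distributions (means
#' 26.1 and 30.8 kg/m^2), couples BMI negatively to the >2 g spike rate
#' (log-linearly), and generates every recording.
#'
#' @param n_healthy,n_stroke group sizes (default 14 each).
#' @param base_healthy,base_stroke base [profile_config()]s.
#' @param seed cohort-level seed driving subject seeds, jitter and BMI.
#' @param bmi_slope log-linear coupling of spike rate to BMI (per kg/m^2).
#' @return A list of subjects, each `list(recording, label, bmi, config)`.
#' @export
generate_cohort <- function(n_healthy = 14, n_stroke = 14,
                            base_healthy = profile_config(),
                            base_stroke = stroke_profile(
                              days = base_healthy$days),
                            seed = 1L, bmi_slope = 0.05) {
  stopifnot(n_healthy >= 1, n_stroke >= 1)
  n <- n_healthy + n_stroke
  draws <- with_seed(seed, list(
    seeds = sample.int(1e9, n),
    jitter = matrix(runif(3 * n, 0.8, 1.25), n),
    bmi = c(rnorm(n_healthy, 26.1, 3.0), rnorm(n_stroke, 30.8, 5.6))))
  lapply(seq_len(n), function(k) {
    stroke <- k > n_healthy
    base <- if (stroke) base_stroke else base_healthy
    mu_bmi <- if (stroke) 30.8 else 26.1
    cfg <- base
    cfg$seed <- as.integer(draws$seeds[k])
    cfg$gait_bout_rate_per_hour <- cfg$gait_bout_rate_per_hour * draws$jitter[k, 1]
    cfg$bout_duration_s <- cfg$bout_duration_s * draws$jitter[k, 2]
    cfg$high_g_event_rate <- cfg$high_g_event_rate * draws$jitter[k, 3] *
      exp(-bmi_slope * (draws$bmi[k] - mu_bmi))
    list(recording = generate_recording(cfg),
         label = cfg$group, bmi = draws$bmi[k], config = cfg)
  })
}

#' Write a cohort manifest
#'
#' One row per subject: id, group label, BMI and generator seed.
#'
#' @param cohort a [generate_cohort()] result.
#' @param path CSV path.
#' @export
write_cohort_manifest <- function(cohort, path) {
  dt <- data.table::data.table(
    subject = seq_along(cohort),
    label = vapply(cohort, `[[`, character(1), "label"),
    bmi = vapply(cohort, `[[`, numeric(1), "bmi"),
    seed = vapply(cohort, function(s) s$config$seed, integer(1)))
  data.table::fwrite(dt, path)
  invisible(path)
}
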