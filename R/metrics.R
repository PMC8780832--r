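#' Higher-acceleration fraction (HAF)
#'
#' The log (base 10 by default) of the fraction of daytime, near-south-pole
#' samples whose resultant acceleration exceeds a high-acceleration threshold
#' (2 g by default): `HAF = log10(n_above / n_selected)`. Always `<= 0`; 0
#' iff every selected sample exceeds the threshold. A markedly negative HAF
#' indicates sedentary behaviour with few vigorous movements.
#'
#' Selection uses the elevation and daytime constraints of `crit` (the bin
#' filter is not applied to the scalar metrics). When no selected sample
#' exceeds the threshold the value is `NA` with `sentinel = "none-above-
#' threshold"` rather than `-Inf`.
#'
#' @param rec an [imu_recording()].
#' @param crit a [selection_criteria()] providing `theta_max` and the daytime
#'   window.
#' @param threshold_g high-acceleration threshold in g (default 2).
#' @param log_base logarithm base (default 10).
#' @return List with `haf`, `n_above`, `n_selected` and `sentinel` (`NA` or a
#'   string).
#' @export
higher_acceleration_fraction <- function(rec, crit = selection_criteria(),
                                         threshold_g = 2, log_base = 10) {
  sel <- elevation_daytime_mask(rec, crit)
  n_sel <- sum(sel)
  if (n_sel == 0L) stop("no samples pass the daytime/elevation selection",
                        call. = FALSE)
  ra <- accel_magnitude(rec)
  n_above <- sum(ra[sel] > threshold_g)
  if (n_above == 0L)
    return(list(haf = NA_real_, n_above = 0L, n_selected = n_sel,
                sentinel = "none-above-threshold"))
  list(haf = log(n_above / n_sel, base = log_base), n_above = n_above,
       n_selected = n_sel, sentinel = NA_character_)
}

#' Acceleration asymmetry index (AAI)
#'
#' Counts the high-acceleration (`|a| >` threshold) samples among the
#' daytime/elevation-selected samples on the participant's right side
#' (`phi < 0`, `n_right`) and left side (`phi >= 0`, `n_left`) and returns
#' `alpha = |log10(n_right / n_left)|`. Symmetric movers have counts near
#' parity and an index near zero; post-stroke movement asymmetry pushes the
#' ratio away from unity. The signed log ratio and the raw counts are
#' returned alongside; if either side has no counts the index is `NA` with a
#' one-sided sentinel.
#'
#' @inheritParams higher_acceleration_fraction
#' @return List with `aai` (absolute log ratio), `aai_signed`, `n_right`,
#'   `n_left`, `sentinel`.
#' @export
acceleration_asymmetry_index <- function(rec, crit = selection_criteria(),
                                         threshold_g = 2, log_base = 10) {
  sph <- to_spherical(rec$accel)
  sel <- elevation_daytime_mask(rec, crit, sph) & sph$rho > threshold_g
  n_right <- sum(sel & sph$phi < 0)
  n_left <- sum(sel & sph$phi >= 0)
  if (n_right == 0L || n_left == 0L)
    return(list(aai = NA_real_, aai_signed = NA_real_, n_right = n_right,
                n_left = n_left, sentinel = "one-sided-counts"))
  s <- log(n_right / n_left, base = log_base)
  list(aai = abs(s), aai_signed = s, n_right = n_right, n_left = n_left,
       sentinel = NA_character_)
}

#' Actigraphic sleep detection
#'
#' Evaluates the acceleration magnitude in the sensor x-z plane,
#' `R = sqrt(ax^2 + az^2)`, over consecutive 1-second windows. A window is
#' flagged as sleep when `[mean - variance, mean + variance]` of `R` lies
#' within the band `[0.97, 1.02]` g — lying postures place gravity in the
#' x-z plane so `R` is pinned near 1 g with very low variability, while
#' upright postures give `R` near zero. Variance (not SD) enters the band
#' test, as the rule is conventionally stated.
#'
#' @param rec an [imu_recording()] of at least 1 s.
#' @param window_s moving-window length in seconds (default 1).
#' @param band lower/upper bounds in g (default `c(0.97, 1.02)`).
#' @return List with per-sample logical `mask`, per-window logical
#'   `window_flags`, and `sleep_hours`.
#' @export
detect_sleep <- function(rec, window_s = 1, band = c(0.97, 1.02)) {
  fs <- rec$sample_rate_hz
  w <- as.integer(round(window_s * fs))
  n <- length(rec$time)
  if (n < w) stop("recording shorter than one window", call. = FALSE)
  r <- sqrt(rec$accel[, 1]^2 + rec$accel[, 3]^2)
  nw <- n %/% w
  m <- matrix(r[seq_len(nw * w)], nrow = w)
  mu <- colMeans(m)
  v <- colMeans(m^2) - mu^2
  flags <- (mu - v) >= band[1] & (mu + v) <= band[2]
  mask <- rep(FALSE, n)
  mask[seq_len(nw * w)] <- rep(flags, each = w)
  list(mask = mask, window_flags = flags,
       sleep_hours = sum(flags) * window_s / 3600)
}

#' Banded activity amplitudes from detrended resultant acceleration
#'
#' The detrended resultant acceleration (DRA) is `| |a| - 1 |` in g — the
#' magnitude with the gravitational baseline removed. Contiguous epochs where
#' DRA rises above a small noise floor are integrated over time
#' (trapezoidal), giving an amplitude in g.s per epoch. Each epoch is
#' assigned to an intensity band (low / medium / high) by its peak DRA
#' against two cut points, and to one of four six-hour time zones
#' (1: 00:00–05:59, 2: 06:00–11:59, 3: 12:00–17:59, 4: 18:00–23:59) by its
#' starting wall-clock time.
#'
#' @param rec an [imu_recording()].
#' @param band_thresholds two increasing cut points in g separating
#'   low/medium and medium/high epochs (default `c(0.1, 0.3)`).
#' @param min_dra noise floor in g below which DRA is treated as zero when
#'   delimiting epochs (default 0.02).
#' @return List with `by_band` (named numeric, g.s), `by_timezone` (named
#'   numeric over zones 1–4), `epochs` (data.frame of per-epoch start time,
#'   duration, peak, amplitude, band, zone) and `total`.
#' @export
activity_amplitude <- function(rec, band_thresholds = c(0.1, 0.3),
                               min_dra = 0.02) {
  if (length(band_thresholds) != 2 || diff(band_thresholds) <= 0)
    stop("band_thresholds must be two increasing cut points", call. = FALSE)
  dra <- abs(accel_magnitude(rec) - 1)
  active <- dra > min_dra
  bands <- c("low", "medium", "high")
  empty <- list(
    by_band = stats::setNames(numeric(3), bands),
    by_timezone = stats::setNames(numeric(4), paste0("zone", 1:4)),
    epochs = data.frame(start_s = numeric(0), duration_s = numeric(0),
                        peak = numeric(0), amplitude = numeric(0),
                        band = character(0), zone = integer(0)),
    total = 0)
  if (!any(active)) return(empty)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  tod <- time_of_day(rec)
  ep <- lapply(seq_along(starts), function(k) {
    i <- starts[k]:ends[k]
    amp <- if (length(i) > 1) trapz_int(rec$time[i], dra[i]) else 0
    c(start_s = rec$time[starts[k]], duration_s =
        rec$time[ends[k]] - rec$time[starts[k]], peak = max(dra[i]),
      amplitude = amp, zone = 1 + (tod[starts[k]] %/% 21600))
  })
  ep <- as.data.frame(do.call(rbind, ep))
  ep$band <- bands[1L + (ep$peak >= band_thresholds[1]) +
                     (ep$peak >= band_thresholds[2])]
  ep$zone <- as.integer(ep$zone)
  by_band <- stats::setNames(vapply(bands, function(b)
    sum(ep$amplitude[ep$band == b]), numeric(1)), bands)
  by_zone <- stats::setNames(vapply(1:4, function(z)
    sum(ep$amplitude[ep$zone == z]), numeric(1)), paste0("zone", 1:4))
  list(by_band = by_band, by_timezone = by_zone, epochs = ep,
       total = sum(ep$amplitude))
}

trapz_int <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Movement-transition detection and statistics
#'
#' Finds peaks of the resultant acceleration with a minimum prominence and a
#' minimum separation, then classifies as a movement transition every peak
#' whose surrounding trough-to-trough span is at most `max_span_s` seconds
#' (postural transitions are brief). For each transition the maximum,
#' minimum, root-mean-square, range and duration of `|a|` over the
#' trough-to-trough segment are reported.
#'
#' Peaks are located on a lightly smoothed magnitude (centred moving average
#' of `smooth_s` seconds) so that sensor noise does not spawn spurious local
#' maxima; the per-transition statistics are computed on the raw magnitude.
#' Prominence is assessed within `2 max_span_s` of each peak, the
#' neighbourhood relevant to short transition events.
#'
#' @param rec an [imu_recording()] of at least a few seconds.
#' @param prominence minimum peak prominence in g (default 0.2).
#' @param min_separation_s minimum spacing between retained peaks (default 1).
#' @param max_span_s maximum trough-to-trough span of a transition (default 3).
#' @param smooth_s moving-average length for peak localisation (default 0.05).
#' @return List with `n_transitions` and a data.frame `transitions` of
#'   per-event statistics (`peak_time_s`, `max`, `min`, `rms`, `range`,
#'   `duration_s`).
#' @export
detect_transitions <- function(rec, prominence = 0.2, min_separation_s = 1,
                               max_span_s = 3, smooth_s = 0.05) {
  ra <- accel_magnitude(rec)
  fs <- rec$sample_rate_hz
  k <- max(1L, as.integer(round(smooth_s * fs)))
  if (k %% 2L == 0L) k <- k + 1L
  ras <- if (k > 1L) {
    s <- as.numeric(stats::filter(ra, rep(1 / k, k), sides = 2))
    s[is.na(s)] <- ra[is.na(s)]
    s
  } else ra
  pk <- find_peaks(ras, prominence = prominence,
                   min_dist = as.integer(round(min_separation_s * fs)),
                   wlen = as.integer(round(2 * max_span_s * fs)))
  empty <- data.frame(peak_time_s = numeric(0), max = numeric(0),
                      min = numeric(0), rms = numeric(0), range = numeric(0),
                      duration_s = numeric(0))
  if (length(pk) == 0L)
    return(list(n_transitions = 0L, transitions = empty))
  # surrounding troughs: magnitude minima between consecutive peaks (or the
  # series ends)
  bounds <- c(1L, length(ra))
  tr <- vapply(seq_along(pk), function(k) {
    lo <- if (k == 1L) bounds[1] else pk[k - 1L]
    hi <- if (k == length(pk)) bounds[2] else pk[k + 1L]
    # ties on flat stretches resolve toward the peak: latest minimum on the
    # left, earliest on the right, so the span hugs the event
    seg_l <- ras[lo:pk[k]]
    left <- lo + (length(seg_l) - which.min(rev(seg_l)))
    right <- pk[k] + which.min(ras[pk[k]:hi]) - 1L
    c(left, right)
  }, integer(2))
  span <- rec$time[tr[2, ]] - rec$time[tr[1, ]]
  keep <- span <= max_span_s
  if (!any(keep)) return(list(n_transitions = 0L, transitions = empty))
  rows <- lapply(which(keep), function(k) {
    seg <- ra[tr[1, k]:tr[2, k]]
    data.frame(peak_time_s = rec$time[pk[k]], max = max(seg), min = min(seg),
               rms = sqrt(mean(seg^2)), range = diff(range(seg)),
               duration_s = span[k])
  })
  out <- do.call(rbind, rows)
  list(n_transitions = nrow(out), transitions = out)
}

# local maxima with a prominence criterion, then greedy enforcement of a
# minimum peak separation (highest peaks win); compiled walk-based search,
# prominence capped at wlen samples per side (0 = uncapped)
find_peaks <- function(x, prominence, min_dist = 1L, wlen = 0L) {
  if (length(x) < 3L) return(integer(0))
  .find_peaks_cpp(as.numeric(x), prominence, as.integer(min_dist),
                  as.integer(wlen))
}

#' Complex Morlet wavelet spectrogram of the acceleration magnitude
#'
#' Convolves the mean-removed resultant acceleration with complex Morlet
#' kernels (a complex sinusoid under a Gaussian envelope) at the requested
#' analysis frequencies; power is the squared magnitude of the complex
#' convolution. The Gaussian has standard deviation `cycles / (2 pi f)`
#' seconds and the kernel is truncated at four standard deviations.
#'
#' @param rec an [imu_recording()], or a numeric signal via `signal`.
#' @param freqs analysis frequencies in Hz, all within `(0, rate/2)`.
#' @param cycles number of wavelet cycles (time-frequency trade-off,
#'   default 7).
#' @param signal optional raw signal overriding `rec`'s magnitude.
#' @param sample_rate_hz required when `signal` is given without `rec`.
#' @return List with `power` (time x frequency matrix), `freqs` and `time_s`.
#' @export
cmw_spectrogram <- function(rec = NULL, freqs, cycles = 7, signal = NULL,
                            sample_rate_hz = NULL) {
  if (is.null(signal)) {
    signal <- accel_magnitude(rec)
    sample_rate_hz <- rec$sample_rate_hz
    time_s <- rec$time
  } else {
    if (is.null(sample_rate_hz)) stop("sample_rate_hz required", call. = FALSE)
    time_s <- (seq_along(signal) - 1) / sample_rate_hz
  }
  if (any(freqs <= 0 | freqs >= sample_rate_hz / 2))
    stop("freqs must lie in (0, rate/2)", call. = FALSE)
  x <- signal - mean(signal)
  n <- length(x)
  power <- matrix(NA_real_, n, length(freqs))
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sd_t <- cycles / (2 * pi * f)
    half <- ceiling(4 * sd_t * sample_rate_hz)
    if (2 * half + 1 > n)
      stop("kernel for ", f, " Hz is longer than the signal", call. = FALSE)
    tt <- (-half:half) / sample_rate_hz
    kern <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sd_t^2))
    kern <- kern / sqrt(sum(Mod(kern)^2))
    # linear convolution by FFT, centre-aligned
    m <- stats::nextn(n + 2 * half)
    X <- fft(c(x, numeric(m - n)))
    K <- fft(c(kern, complex(real = numeric(m - 2 * half - 1))))
    conv <- fft(X * K, inverse = TRUE) / m
    power[, k] <- Mod(conv[(half + 1):(half + n)])^2
  }
  list(power = power, freqs = freqs, time_s = time_s)
}

#' Cohen's d effect size
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled` with the
#' pooled standard deviation weighted by `n - 1`. Zero pooled SD yields `NA`.
#'
#' @param a,b numeric vectors with at least 2 values each.
#' @return Numeric scalar.
#' @export
cohens_d <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Per-recording movement metric report
#'
#' Computes every scalar movement metric for one recording: the
#' higher-acceleration fraction, the acceleration asymmetry index with its
#' side counts, actigraphic sleep hours, banded activity amplitudes with
#' per-time-zone totals, and the movement-transition count. The thresholds
#' in force are echoed into the report.
#'
#' @param rec an [imu_recording()].
#' @param crit a [selection_criteria()] (daytime + elevation constraints for
#'   HAF/AAI).
#' @param threshold_g high-acceleration threshold in g.
#' @param log_base log base for HAF/AAI.
#' @param band_thresholds activity-amplitude cut points in g.
#' @return An object of class `metric_report`.
#' @export
movement_metrics <- function(rec, crit = selection_criteria(),
                             threshold_g = 2, log_base = 10,
                             band_thresholds = c(0.1, 0.3)) {
  haf <- tryCatch(
    higher_acceleration_fraction(rec, crit, threshold_g, log_base),
    error = function(e) list(haf = NA_real_, n_above = 0L, n_selected = 0L,
                             sentinel = "empty-selection"))
  aai <- acceleration_asymmetry_index(rec, crit, threshold_g, log_base)
  slp <- detect_sleep(rec)
  aa <- activity_amplitude(rec, band_thresholds)
  tr <- detect_transitions(rec)
  structure(
    list(haf = haf$haf, haf_counts = haf[c("n_above", "n_selected")],
         haf_sentinel = haf$sentinel,
         aai = aai$aai, aai_signed = aai$aai_signed,
         n_left = aai$n_left, n_right = aai$n_right,
         aai_sentinel = aai$sentinel,
         sleep_hours = slp$sleep_hours,
         activity_amplitude = aa$by_band, aa_by_timezone = aa$by_timezone,
         n_transitions = tr$n_transitions,
         config = list(threshold_g = threshold_g, log_base = log_base,
                       band_thresholds = band_thresholds,
                       theta_max = crit$theta_max,
                       day_start = crit$day_start, day_end = crit$day_end)),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  cat(sprintf("  HAF: %s  (%d / %d samples > %g g)\n",
              fmt_or_sentinel(x$haf, x$haf_sentinel), x$haf_counts$n_above,
              x$haf_counts$n_selected, x$config$threshold_g))
  cat(sprintf("  AAI: %s  (right %d / left %d)\n",
              fmt_or_sentinel(x$aai, x$aai_sentinel), x$n_right, x$n_left))
  cat(sprintf("  sleep: %.2f h;  transitions: %d\n", x$sleep_hours,
              x$n_transitions))
  cat("  activity amplitude (g.s):",
      paste(names(x$activity_amplitude),
            sprintf("%.3g", x$activity_amplitude), collapse = ", "), "\n")
  invisible(x)
}

fmt_or_sentinel <- function(v, s) {
  if (!is.na(s)) paste0("<", s, ">") else sprintf("%.4f", v)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(haf = x$haf, aai = x$aai, aai_signed = x$aai_signed,
             n_left = x$n_left, n_right = x$n_right,
             sleep_hours = x$sleep_hours,
             aa_low = x$activity_amplitude[["low"]],
             aa_medium = x$activity_amplitude[["medium"]],
             aa_high = x$activity_amplitude[["high"]],
             aa_zone1 = x$aa_by_timezone[["zone1"]],
             aa_zone2 = x$aa_by_timezone[["zone2"]],
             aa_zone3 = x$aa_by_timezone[["zone3"]],
             aa_zone4 = x$aa_by_timezone[["zone4"]],
             n_transitions = x$n_transitions)
}

#' Write a metric report as JSON
#'
#' @param report a [movement_metrics()] result.
#' @param path output path.
#' @export
write_metric_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
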