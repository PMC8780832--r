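#' Criteria for information-rich sample selection
#'
#' Encodes the three filters that isolate movement-bearing samples from a
#' multi-day recording: (1) elevation restricted to a neighbourhood of the
#' south pole, `theta` in `[-pi/2, theta_max]`, because upright activity
#' happens near the standing gravity direction; (2) a daytime wall-clock
#' window; (3) a bin-statistics filter that discards orientation bins whose
#' magnitude distribution looks like rest (standard deviation below `sd_min`
#' combined with mean within `mean_dev_min` of 1 g).
#'
#' The bin filter's combination rule is configurable: `"AND"` keeps a bin
#' when `sd >= sd_min` **and** `|mean - 1| > mean_dev_min`; `"OR"` keeps it
#' when either holds (excluding only bins that are both low-variability and
#' near-gravity). `"AND"` is the default, literal reading; `"OR"` matches the
#' rest-exclusion rationale and is provided as a switch.
#'
#' @param theta_max upper elevation bound in radians (negative; default
#'   `-pi/3`).
#' @param sd_min minimum per-bin SD of `|a|` in g (default 0.02).
#' @param mean_dev_min minimum `|mean(|a|) - 1|` in g (default 0.02).
#' @param day_start,day_end daytime window as `"HH:MM"` local wall-clock
#'   (default 07:00–20:00, half-open).
#' @param combine_rule `"AND"` or `"OR"` for the bin filter.
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(theta_max = -pi / 3, sd_min = 0.02,
                               mean_dev_min = 0.02, day_start = "07:00",
                               day_end = "20:00",
                               combine_rule = c("AND", "OR")) {
  stopifnot(theta_max < 0, sd_min >= 0, mean_dev_min >= 0)
  ds <- parse_hhmm(day_start)
  de <- parse_hhmm(day_end)
  if (ds >= de) stop("day_start must precede day_end", call. = FALSE)
  structure(list(theta_max = theta_max, sd_min = sd_min,
                 mean_dev_min = mean_dev_min, day_start = day_start,
                 day_end = day_end, day_start_s = ds, day_end_s = de,
                 combine_rule = match.arg(combine_rule)),
            class = "selection_criteria")
}

parse_hhmm <- function(x) {
  if (is.numeric(x)) return(x)
  p <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
  p[1] * 3600 + p[2] * 60
}

#' @export
print.selection_criteria <- function(x, ...) {
  cat("<selection_criteria>\n")
  cat(sprintf("  elevation: theta in [-pi/2, %.4f] rad\n", x$theta_max))
  cat(sprintf("  bin filter: sd >= %g %s |mean - 1| > %g (g)\n",
              x$sd_min, x$combine_rule, x$mean_dev_min))
  cat("  daytime:", x$day_start, "to", x$day_end, "\n")
  invisible(x)
}

# elevation + daytime mask only (the constraint set used by the scalar
# metrics, which do not apply the bin filter)
elevation_daytime_mask <- function(rec, crit, sph = NULL) {
  if (is.null(sph)) sph <- to_spherical(rec$accel)
  tod <- time_of_day(rec)
  sph$theta <= crit$theta_max & tod >= crit$day_start_s & tod < crit$day_end_s
}

#' Select information-rich samples
#'
#' Applies the three filters of [selection_criteria()] per sample: elevation,
#' daytime wall-clock, and the statistics of the sample's orientation bin.
#' Bins with missing statistics (empty bins can't occur for samples that
#' land in them; single-sample bins have SD 0) fail the SD test.
#'
#' @param rec an [imu_recording()].
#' @param grid a [compute_bin_grid()] result for `rec` (or a reference grid
#'   with the same binning).
#' @param crit a [selection_criteria()].
#' @return Logical mask over the samples of `rec`.
#' @export
select_samples <- function(rec, grid, crit = selection_criteria()) {
  if (!inherits(grid, "bin_grid")) stop("`grid` must be a bin_grid", call. = FALSE)
  if (grid$n_total != length(rec$time))
    warning("grid was computed from a different number of samples; ",
            "treating it as a reference grid")
  sph <- to_spherical(rec$accel)
  base <- elevation_daytime_mask(rec, crit, sph)
  b <- bin_index(sph$theta, sph$phi)
  at <- cbind(b$i, b$j)
  sd_ok <- grid$sd_a[at] >= crit$sd_min
  mean_ok <- abs(grid$mean_a[at] - 1) > crit$mean_dev_min
  sd_ok[is.na(sd_ok)] <- FALSE
  mean_ok[is.na(mean_ok)] <- FALSE
  bin_ok <- if (crit$combine_rule == "AND") sd_ok & mean_ok else sd_ok | mean_ok
  base & bin_ok
}

#' Cut masked samples into fixed-length feature windows
#'
#' Within each maximal contiguous run of selected samples (runs also break at
#' timestamp gaps larger than `1.5 / sample_rate`), consecutive
#' non-overlapping windows of `window_s` seconds are taken left to right;
#' a run of `L` samples yields `floor(L / (window_s * rate))` windows and
#' short runs yield none. Each window carries 12 feature channels per
#' timestep: the raw triaxial acceleration and angular velocity, the
#' resultant `|a|`, the three components of the sample's projection on the
#' unit acceleration sphere, and the two sphere angles.
#'
#' @param rec an [imu_recording()].
#' @param mask logical sample mask from [select_samples()] (or any mask of
#'   the same length).
#' @param window_s window length in seconds (default 3).
#' @param stride window stride in samples; defaults to the window length
#'   (non-overlapping).
#' @param label optional group label attached to every window; defaults to
#'   `rec$subject_meta$group`.
#' @return An object of class `window_set`: `features` array
#'   `n_windows x timesteps x 12`, `label` vector, `start_clock` POSIXct
#'   vector, and the windowing parameters.
#' @export
segment_windows <- function(rec, mask, window_s = 3, stride = NULL,
                            label = NULL) {
  n <- length(rec$time)
  stopifnot(length(mask) == n)
  fs <- rec$sample_rate_hz
  L <- as.integer(round(window_s * fs))
  if (is.null(stride)) stride <- L
  if (is.null(label)) label <- rec$subject_meta$group
  gap <- c(FALSE, diff(rec$time) > 1.5 / fs)
  runid <- cumsum(gap | (mask & !c(FALSE, mask[-n])))
  runid[!mask] <- 0L
  starts <- integer(0)
  if (any(mask)) {
    idx <- which(mask)
    rid <- runid[idx]
    # first index and length of every maximal run
    first <- idx[!duplicated(rid)]
    len <- as.integer(table(factor(rid, levels = unique(rid))))
    for (k in seq_along(first)) {
      nw <- if (len[k] < L) 0L else (len[k] - L) %/% stride + 1L
      if (nw > 0L)
        starts <- c(starts, first[k] + stride * (0:(nw - 1L)))
    }
  }
  nw <- length(starts)
  feats <- window_feature_names()
  arr <- array(NA_real_, c(nw, L, 12L),
               dimnames = list(NULL, NULL, feats))
  if (nw > 0L) {
    sph <- to_spherical(rec$accel)
    uas <- rec$accel / sph$rho
    chan <- cbind(rec$accel, rec$gyro, sph$rho, uas, sph$phi, sph$theta)
    take <- outer(starts, 0:(L - 1L), `+`)  # nw x L index matrix
    for (c in 1:12) arr[, , c] <- chan[take, c]
  }
  structure(
    list(features = arr,
         label = if (is.null(label)) rep(NA_character_, nw)
                 else rep(as.character(label), nw),
         start_clock = rec$start_clock + if (nw) rec$time[starts] else numeric(0),
         window_s = window_s, sample_rate_hz = fs, timesteps = L),
    class = "window_set")
}

window_feature_names <- function() {
  c("ax", "ay", "az", "gx", "gy", "gz", "ra", "axs", "ays", "azs",
    "phi", "theta")
}

#' @export
print.window_set <- function(x, ...) {
  cat("<window_set>", n_windows(x), "windows of", x$timesteps, "timesteps x",
      dim(x$features)[3], "channels\n")
  if (any(!is.na(x$label))) print(table(x$label))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws a [segment_windows()] result.
#' @export
n_windows <- function(ws) dim(ws$features)[1]

#' @export
`[.window_set` <- function(x, i, ...) {
  structure(
    list(features = x$features[i, , , drop = FALSE], label = x$label[i],
         start_clock = x$start_clock[i], window_s = x$window_s,
         sample_rate_hz = x$sample_rate_hz, timesteps = x$timesteps),
    class = "window_set")
}

#' Concatenate window sets
#' @param ... `window_set` objects with identical window geometry.
#' @return A single `window_set`.
#' @export
bind_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "window_set")) sets <- sets[[1]]
  stopifnot(length(sets) >= 1)
  L <- sets[[1]]$timesteps
  if (!all(vapply(sets, function(s) s$timesteps == L, logical(1))))
    stop("window sets have differing geometry", call. = FALSE)
  feats <- do.call(rbind, lapply(sets, function(s)
    matrix(s$features, nrow = n_windows(s))))
  arr <- array(feats, c(nrow(feats), L, 12L),
               dimnames = list(NULL, NULL, window_feature_names()))
  structure(
    list(features = arr,
         label = unlist(lapply(sets, `[[`, "label"), use.names = FALSE),
         start_clock = do.call(c, lapply(sets, `[[`, "start_clock")),
         window_s = sets[[1]]$window_s,
         sample_rate_hz = sets[[1]]$sample_rate_hz, timesteps = L),
    class = "window_set")
}

#' Deterministic shuffled train/validation split
#'
#' Randomly shuffles the windows and partitions them, `train_frac` to the
#' training set and the remainder to validation. Labels travel with their
#' windows; the split is a partition and is identical for identical seeds.
#'
#' @param ws a `window_set`.
#' @param train_frac fraction in (0, 1), default 0.8.
#' @param seed integer seed.
#' @return `list(train = window_set, val = window_set)`.
#' @export
split_train_val <- function(ws, train_frac = 0.8, seed = 1L) {
  if (!(train_frac > 0 && train_frac < 1))
    stop("train_frac must be in (0, 1)", call. = FALSE)
  n <- n_windows(ws)
  if (n < 2L) stop("need at least 2 windows to split", call. = FALSE)
  ord <- with_seed(seed, sample.int(n))
  ntr <- floor(train_frac * n)
  list(train = ws[ord[seq_len(ntr)]], val = ws[ord[(ntr + 1):n]])
}

#' Serialize a window archive
#'
#' Stores the 3-D feature array, the label vector and a JSON sidecar with the
#' selection criteria used, in the binary cache format.
#'
#' @param ws a `window_set`.
#' @param path archive path.
#' @param crit the [selection_criteria()] that produced the windows (recorded
#'   in the sidecar), or `NULL`.
#' @export
write_window_archive <- function(ws, path, crit = NULL) {
  saveRDS(list(format = "adlsphere-window-archive", version = 1L,
               features = ws$features, label = ws$label,
               start_clock = ws$start_clock, window_s = ws$window_s,
               sample_rate_hz = ws$sample_rate_hz, timesteps = ws$timesteps),
          path)
  if (!is.null(crit))
    jsonlite::write_json(
      crit[c("theta_max", "sd_min", "mean_dev_min", "day_start", "day_end",
             "combine_rule")],
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_window_archive
#' @export
read_window_archive <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "adlsphere-window-archive"))
    stop("not a window archive: ", path, call. = FALSE)
  structure(x[c("features", "label", "start_clock", "window_s",
                "sample_rate_hz", "timesteps")],
            class = "window_set")
}
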