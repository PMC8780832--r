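#' Construct an IMU recording
#'
#' The canonical in-memory representation of a continuous inertial recording:
#' float timestamps in seconds from the start of the recording, triaxial
#' acceleration in units of g (1 g = 9.81 m/s^2) and triaxial angular velocity
#' in deg/s, plus one wall-clock anchor for the first sample so time-of-day
#' filters work without per-sample datetimes. Sensor-off gaps are represented
#' by jumps in the timestamp vector, never by NaN padding.
#'
#' The sensor convention is waist-worn with +x toward the participant's left,
#' +y vertically up (opposing gravity) and +z posterior, so quiet upright
#' standing reads approximately `a = (0, -1, 0)` g.
#'
#' @param time numeric vector of seconds since recording start, strictly
#'   increasing, nominally spaced `1/sample_rate_hz`.
#' @param accel n x 3 numeric matrix of acceleration `(ax, ay, az)` in g.
#' @param gyro n x 3 numeric matrix of angular velocity `(gx, gy, gz)` in
#'   deg/s, or `NULL` for an accelerometer-only recording (stored as zeros).
#' @param sample_rate_hz nominal sampling rate in Hz.
#' @param start_clock wall-clock datetime of sample 0 (`POSIXct` or a string
#'   understood by [as.POSIXct()]).
#' @param subject_meta optional named list of subject metadata (e.g. `group`,
#'   `bmi`, `age`, `sex`).
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(time, accel, gyro = NULL, sample_rate_hz = 100,
                          start_clock = as.POSIXct("2021-06-07 00:00:00", tz = "UTC"),
                          subject_meta = list()) {
  time <- as.numeric(time)
  accel <- as_matrix3(accel, "accel")
  n <- length(time)
  if (nrow(accel) != n)
    stop("`accel` must have one row per timestamp", call. = FALSE)
  if (is.null(gyro)) gyro <- matrix(0, n, 3) else gyro <- as_matrix3(gyro, "gyro")
  if (nrow(gyro) != n)
    stop("`gyro` must have one row per timestamp", call. = FALSE)
  if (n > 1 && any(diff(time) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (anyNA(accel) || any(!is.finite(accel)))
    stop("`accel` must be finite", call. = FALSE)
  if (is.character(start_clock))
    start_clock <- as.POSIXct(start_clock, tz = "UTC")
  colnames(accel) <- c("ax", "ay", "az")
  colnames(gyro) <- c("gx", "gy", "gz")
  structure(
    list(time = time, accel = accel, gyro = gyro,
         sample_rate_hz = as.numeric(sample_rate_hz),
         start_clock = start_clock, subject_meta = subject_meta),
    class = "imu_recording")
}

as_matrix3 <- function(x, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3) stop("`", what, "` must have 3 columns", call. = FALSE)
  x
}

#' @export
print.imu_recording <- function(x, ...) {
  n <- length(x$time)
  dur <- if (n) x$time[n] - x$time[1] else 0
  cat("<imu_recording> ", n, " samples @ ", x$sample_rate_hz, " Hz (",
      sprintf("%.2f", dur / 3600), " h)\n", sep = "")
  cat("  start:", format(x$start_clock, usetz = TRUE), "\n")
  if (!is.null(x$subject_meta$group))
    cat("  group:", x$subject_meta$group, "\n")
  invisible(x)
}

#' @export
summary.imu_recording <- function(object, ...) {
  ra <- accel_magnitude(object)
  out <- list(
    n = length(object$time),
    duration_h = diff(range(object$time)) / 3600,
    sample_rate_hz = object$sample_rate_hz,
    magnitude = summary(ra),
    gaps = sum(diff(object$time) > 1.5 / object$sample_rate_hz))
  class(out) <- "summary.imu_recording"
  out
}

#' @export
print.summary.imu_recording <- function(x, ...) {
  cat("IMU recording:", x$n, "samples,", sprintf("%.2f h", x$duration_h),
      "at", x$sample_rate_hz, "Hz;", x$gaps, "timestamp gap(s)\n")
  cat("|a| (g):\n")
  print(x$magnitude)
  invisible(x)
}

#' Resultant acceleration magnitude
#'
#' @param rec an [imu_recording()].
#' @return numeric vector of `|a| = sqrt(ax^2 + ay^2 + az^2)` in g.
#' @export
accel_magnitude <- function(rec) {
  sqrt(rowSums(rec$accel^2))
}

#' Wall-clock second-of-day for every sample
#'
#' @param rec an [imu_recording()].
#' @return numeric vector in `[0, 86400)`.
#' @export
time_of_day <- function(rec) {
  lt <- as.POSIXlt(rec$start_clock)
  anchor <- lt$hour * 3600 + lt$min * 60 + lt$sec
  (anchor + rec$time) %% 86400
}

#' Declare the column layout and units of a delimited IMU file
#'
#' @param time,ax,ay,az,gx,gy,gz column names in the file.
#' @param accel_units `"g"` or `"ms2"`; m/s^2 values are divided by 9.81.
#' @param gyro_units `"degs"` or `"rads"`; rad/s values are converted to deg/s.
#' @param delim field delimiter.
#' @return A named list of class `imu_schema`.
#' @export
imu_schema <- function(time = "time", ax = "ax", ay = "ay", az = "az",
                       gx = "gx", gy = "gy", gz = "gz",
                       accel_units = c("g", "ms2"),
                       gyro_units = c("degs", "rads"), delim = ",") {
  structure(list(time = time, ax = ax, ay = ay, az = az,
                 gx = gx, gy = gy, gz = gz,
                 accel_units = match.arg(accel_units),
                 gyro_units = match.arg(gyro_units), delim = delim),
            class = "imu_schema")
}

#' Read an IMU recording from delimited text
#'
#' Values are converted to canonical units (g and deg/s). Rows containing
#' non-finite channel values are dropped with a message; non-monotone
#' timestamps are a data error.
#'
#' @param path file to read.
#' @param schema an [imu_schema()] naming the timestamp and six channel
#'   columns and declaring their units.
#' @param sample_rate_hz,start_clock,subject_meta recording metadata not
#'   carried by the delimited format; see [imu_recording()].
#' @return An [imu_recording()].
#' @export
read_imu_csv <- function(path, schema = imu_schema(), sample_rate_hz = 100,
                         start_clock = as.POSIXct("2021-06-07 00:00:00", tz = "UTC"),
                         subject_meta = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = schema$delim)
  cols <- unlist(schema[c("time", "ax", "ay", "az", "gx", "gy", "gz")])
  missing <- setdiff(cols, names(dt))
  if (length(missing))
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(dt[, cols, with = FALSE])
  ok <- rowSums(!is.finite(m)) == 0
  if (!all(ok)) {
    message("dropping ", sum(!ok), " row(s) with non-finite values")
    m <- m[ok, , drop = FALSE]
  }
  if (nrow(m) > 1 && any(diff(m[, 1]) <= 0))
    stop("data error: timestamps are not strictly increasing", call. = FALSE)
  accel <- m[, 2:4, drop = FALSE]
  gyro <- m[, 5:7, drop = FALSE]
  if (schema$accel_units == "ms2") accel <- accel / 9.81
  if (schema$gyro_units == "rads") gyro <- gyro * (180 / pi)
  imu_recording(m[, 1], accel, gyro, sample_rate_hz = sample_rate_hz,
                start_clock = start_clock, subject_meta = subject_meta)
}

#' Write an IMU recording as delimited text
#'
#' Writes a header row with canonical column names `time, ax, ay, az, gx, gy,
#' gz`. Numeric values round-trip through [read_imu_csv()] to within 1e-9 g.
#'
#' @param rec an [imu_recording()].
#' @param path output file.
#' @param delim field delimiter.
#' @export
write_imu_csv <- function(rec, path, delim = ",") {
  dt <- data.table::data.table(
    time = rec$time,
    ax = rec$accel[, 1], ay = rec$accel[, 2], az = rec$accel[, 3],
    gx = rec$gyro[, 1], gy = rec$gyro[, 2], gz = rec$gyro[, 3])
  data.table::fwrite(dt, path, sep = delim)
  invisible(path)
}

#' Binary cache for IMU recordings
#'
#' A single-file binary container holding one dataset per channel plus the
#' `sample_rate_hz` and `start_clock` attributes, via R's native
#' serialization. Round-trips are exact.
#'
#' @param rec an [imu_recording()].
#' @param path cache file path.
#' @export
write_imu_cache <- function(rec, path) {
  saveRDS(list(format = "adlsphere-imu-cache", version = 1L,
               time = rec$time, accel = rec$accel, gyro = rec$gyro,
               sample_rate_hz = rec$sample_rate_hz,
               start_clock = rec$start_clock,
               subject_meta = rec$subject_meta),
          path)
  invisible(path)
}

#' @rdname write_imu_cache
#' @export
read_imu_cache <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "adlsphere-imu-cache"))
    stop("not an adlsphere IMU cache: ", path, call. = FALSE)
  imu_recording(x$time, x$accel, x$gyro, x$sample_rate_hz, x$start_clock,
                x$subject_meta)
}
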