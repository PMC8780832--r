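#' Transform acceleration vectors to spherical coordinates
#'
#' Maps Cartesian acceleration samples `(ax, ay, az)` in g to spherical
#' coordinates: magnitude `rho = sqrt(ax^2 + ay^2 + az^2)`, elevation
#' `theta = atan2(ay, sqrt(ax^2 + az^2))` measured from the equatorial x-z
#' plane (so quiet upright standing, `a = (0, -1, 0)`, sits at the south pole
#' `theta = -pi/2`), and azimuth `phi`. The default azimuth convention is
#' `phi = atan2(ax, -az)`, which spans `[-pi, pi]`, maps the participant's
#' left (+x) to `phi = +pi/2`, and makes `phi = 0` the left/right split used
#' by the asymmetry index. At the poles (`ax = az = 0`) the azimuth is
#' undefined and the convention `phi = 0` is returned.
#'
#' @param a length-3 numeric vector or n x 3 matrix of accelerations in g.
#' @param phi_convention `"neg_z"` for `atan2(ax, -az)` (default) or
#'   `"pos_z"` for `atan2(ax, az)`.
#' @return A data.frame with columns `rho`, `theta`, `phi` (radians).
#' @export
to_spherical <- function(a, phi_convention = c("neg_z", "pos_z")) {
  phi_convention <- match.arg(phi_convention)
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (any(!is.finite(a))) stop("acceleration must be finite", call. = FALSE)
  rho <- sqrt(rowSums(a^2))
  if (any(rho == 0))
    stop("zero acceleration vector has no direction", call. = FALSE)
  rxz <- sqrt(a[, 1]^2 + a[, 3]^2)
  theta <- atan2(a[, 2], rxz)
  z <- if (phi_convention == "neg_z") -a[, 3] else a[, 3]
  phi <- atan2(a[, 1], z)
  phi[rxz == 0] <- 0
  data.frame(rho = rho, theta = theta, phi = phi)
}

#' Invert the spherical transform
#'
#' @param rho,theta,phi spherical coordinates as produced by [to_spherical()].
#' @param phi_convention see [to_spherical()].
#' @return n x 3 matrix of Cartesian accelerations.
#' @export
spherical_to_cartesian <- function(rho, theta, phi,
                                   phi_convention = c("neg_z", "pos_z")) {
  phi_convention <- match.arg(phi_convention)
  ax <- rho * cos(theta) * sin(phi)
  ay <- rho * sin(theta)
  az <- rho * cos(theta) * cos(phi)
  if (phi_convention == "neg_z") az <- -az
  cbind(ax = ax, ay = ay, az = az)
}

#' Project spherical points onto the unit acceleration sphere
#'
#' Sets the radial coordinate to one while keeping both angles, i.e. keeps
#' only the orientation of each acceleration sample. Idempotent.
#'
#' @param p data.frame with `rho`, `theta`, `phi` columns.
#' @return The same data.frame with `rho` replaced by 1.
#' @export
project_to_uas <- function(p) {
  p$rho <- rep(1, nrow(p))
  p
}

#' Assign spherical angles to 1-degree orientation bins
#'
#' The sphere surface is discretized into 360 azimuth x 180 elevation bins of
#' 1 degree each. Bin edges are half-open `[lo, hi)` with the top edge closed
#' (`phi = pi` falls in bin 360, `theta = pi/2` in bin 180), so the 64,800
#' bins partition the closed angle ranges exactly.
#'
#' @param theta,phi angles in radians, `theta` in `[-pi/2, pi/2]` and `phi`
#'   in `[-pi, pi]`.
#' @return A list with integer vectors `i` (azimuth bin, 1..360) and `j`
#'   (elevation bin, 1..180).
#' @export
bin_index <- function(theta, phi) {
  if (any(theta < -pi / 2 - 1e-12 | theta > pi / 2 + 1e-12))
    stop("theta out of [-pi/2, pi/2]", call. = FALSE)
  if (any(phi < -pi - 1e-12 | phi > pi + 1e-12))
    stop("phi out of [-pi, pi]", call. = FALSE)
  i <- pmin(floor((phi + pi) / (2 * pi / 360)) + 1L, 360L)
  j <- pmin(floor((theta + pi / 2) / (pi / 180)) + 1L, 180L)
  list(i = pmax(as.integer(i), 1L), j = pmax(as.integer(j), 1L))
}

#' Per-bin statistics of the acceleration magnitude on the UAS
#'
#' Computes, for every 1-degree orientation bin, the sample count, the
#' empirical probability (count / total), and the mean and standard deviation
#' of the raw per-sample magnitude `|a|` of the samples assigned to the bin.
#' Empty bins have missing (`NA`) mean and SD — never zero — so that they can
#' not masquerade as low-variability rest bins in downstream selection
#' filters; single-sample bins have SD 0.
#'
#' @param rec an [imu_recording()].
#' @param sd_type `"population"` (divide by n, default: bins are descriptive
#'   summaries) or `"sample"` (divide by n - 1).
#' @param phi_convention see [to_spherical()].
#' @return An object of class `bin_grid`: 360 x 180 matrices `counts`,
#'   `prob`, `mean_a`, `sd_a` (azimuth bin x elevation bin) plus `n_total`.
#' @export
compute_bin_grid <- function(rec, sd_type = c("population", "sample"),
                             phi_convention = c("neg_z", "pos_z")) {
  sd_type <- match.arg(sd_type)
  n <- length(rec$time)
  if (n == 0L) stop("empty recording", call. = FALSE)
  sph <- to_spherical(rec$accel, phi_convention = match.arg(phi_convention))
  b <- bin_index(sph$theta, sph$phi)
  idx <- (b$j - 1L) * 360L + b$i
  nb <- 360L * 180L
  counts <- tabulate(idx, nbins = nb)
  s1 <- numeric(nb)
  s2 <- numeric(nb)
  agg <- rowsum(cbind(sph$rho, sph$rho^2), idx)
  at <- as.integer(rownames(agg))
  s1[at] <- agg[, 1]
  s2[at] <- agg[, 2]
  mean_a <- ifelse(counts > 0, s1 / pmax(counts, 1), NA_real_)
  v <- s2 / pmax(counts, 1) - mean_a^2
  v[v < 0] <- 0
  if (sd_type == "sample")
    v <- ifelse(counts > 1, v * counts / (counts - 1), 0)
  sd_a <- sqrt(v)
  sd_a[counts == 1] <- 0
  sd_a[counts == 0] <- NA_real_
  shape <- function(x) matrix(x, 360, 180)
  structure(
    list(counts = shape(counts), prob = shape(counts / n),
         mean_a = shape(mean_a), sd_a = shape(sd_a),
         n_total = n, sd_type = sd_type),
    class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  occ <- sum(x$counts > 0)
  cat("<bin_grid> 360 x 180 one-degree bins;", x$n_total, "samples in", occ,
      "occupied bins\n")
  cat("  max bin probability:", sprintf("%.4g", max(x$prob)), "\n")
  invisible(x)
}

#' Export / import bin-grid statistics as delimited text
#'
#' One file per statistic, each a 360 x 180 matrix (rows = azimuth bin index,
#' columns = elevation bin index, both 1-based, 1-degree bins), plus a JSON
#' sidecar with `n_total` and the SD convention.
#'
#' @param grid a [compute_bin_grid()] result.
#' @param prefix path prefix; files `<prefix>_counts.csv` etc. are written.
#' @export
write_bin_grid <- function(grid, prefix) {
  for (s in c("counts", "prob", "mean_a", "sd_a"))
    data.table::fwrite(data.table::as.data.table(grid[[s]]),
                       paste0(prefix, "_", s, ".csv"), col.names = FALSE)
  jsonlite::write_json(list(n_total = grid$n_total, sd_type = grid$sd_type),
                       paste0(prefix, "_meta.json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_bin_grid
#' @export
read_bin_grid <- function(prefix) {
  rd <- function(s) as.matrix(data.table::fread(
    paste0(prefix, "_", s, ".csv"), header = FALSE))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"))
  g <- list(counts = unname(rd("counts")), prob = unname(rd("prob")),
            mean_a = unname(rd("mean_a")), sd_a = unname(rd("sd_a")),
            n_total = meta$n_total, sd_type = meta$sd_type)
  class(g) <- "bin_grid"
  g
}

#' Polar hemisphere view of a bin-grid statistic
#'
#' Restricts one per-bin statistic to the northern (`theta >= 0`) or southern
#' (`theta < 0`) hemisphere and lays it out as a polar field viewed along the
#' y-axis: angle = azimuth `phi`, radius = colatitude `pi/2 - |theta|`, so the
#' pole sits at the centre. Empty bins are missing; with `log_scale` the
#' base-10 log of the probability is taken and zero-probability bins stay
#' missing rather than `-Inf`.
#'
#' @param grid a [compute_bin_grid()] result.
#' @param which `"north"` or `"south"`.
#' @param statistic `"prob"`, `"mean"` or `"sd"`.
#' @param log_scale logical; log10 display scale (probability only).
#' @return An object of class `hemisphere_view`: a 360 x 90 matrix `values`
#'   (azimuth bin x colatitude ring, ring 1 nearest the pole) plus axis
#'   vectors `phi_deg` and `colat_deg`.
#' @export
hemisphere_view <- function(grid, which = c("south", "north"),
                            statistic = c("prob", "mean", "sd"),
                            log_scale = FALSE) {
  which <- match.arg(which)
  statistic <- match.arg(statistic)
  if (log_scale && statistic != "prob")
    stop("log scale applies to the probability view only", call. = FALSE)
  field <- switch(statistic, prob = grid$prob, mean = grid$mean_a,
                  sd = grid$sd_a)
  if (statistic == "prob") field[grid$counts == 0] <- NA_real_
  # elevation bin j covers theta [-pi/2 + (j-1)deg, ...); south: j in 1..90.
  # Ring 1 is nearest the pole: j = 1 (south, theta = -pi/2) or j = 180 (north).
  jj <- if (which == "south") 1:90 else 180:91
  vals <- field[, jj, drop = FALSE]  # column 1 = ring nearest the pole
  if (log_scale) {
    pos <- !is.na(vals) & vals > 0
    vals[!pos] <- NA_real_
    vals[pos] <- log10(vals[pos])
  }
  structure(
    list(values = vals, phi_deg = seq(-179.5, 179.5, by = 1),
         colat_deg = seq(0.5, 89.5, by = 1), which = which,
         statistic = statistic, log_scale = log_scale),
    class = "hemisphere_view")
}

#' @export
print.hemisphere_view <- function(x, ...) {
  cat("<hemisphere_view>", x$which, "hemisphere,", x$statistic,
      if (x$log_scale) "(log10)" else "", "\n")
  cat("  non-missing bins:", sum(!is.na(x$values)), "of", length(x$values), "\n")
  invisible(x)
}

#' @describeIn hemisphere_view Rasterize and draw the polar field with the
#'   pole at the centre; pixels outside the disc or over empty bins are blank.
#' @param x a `hemisphere_view`.
#' @param npix raster resolution in pixels per side.
#' @param col colour palette.
#' @param ... passed to [graphics::image()].
#' @export
plot.hemisphere_view <- function(x, npix = 400,
                                 col = grDevices::hcl.colors(64, "viridis"),
                                 ...) {
  gx <- seq(-90, 90, length.out = npix)
  px <- matrix(gx, npix, npix)
  py <- matrix(gx, npix, npix, byrow = TRUE)
  r <- sqrt(px^2 + py^2)
  ang <- atan2(py, px) * 180 / pi  # [-180, 180]
  ii <- pmin(pmax(ceiling(ang + 180), 1L), 360L)
  rr <- pmin(ceiling(r), 90L)
  z <- matrix(NA_real_, npix, npix)
  inside <- r <= 90
  z[inside] <- x$values[cbind(ii[inside], rr[inside])]
  graphics::image(gx, gx, z, asp = 1, col = col, xlab = "", ylab = "",
                  axes = FALSE,
                  main = paste(x$which, "hemisphere:", x$statistic,
                               if (x$log_scale) "(log10)" else ""), ...)
  graphics::symbols(0, 0, circles = 90, inches = FALSE, add = TRUE,
                    fg = "grey40")
  invisible(x)
}
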