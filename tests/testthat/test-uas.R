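test_that("canonical orientations map to the documented sphere points", {
  # upright standing: gravity along -y is the south pole
  p <- to_spherical(c(0, -1, 0))
  expect_equal(p$rho, 1)
  expect_equal(p$theta, -pi / 2)
  expect_equal(p$phi, 0)  # pole convention
  # +x (participant's left) sits on the equator at phi = +pi/2
  p <- to_spherical(c(1, 0, 0))
  expect_equal(p$theta, 0)
  expect_equal(p$phi, pi / 2)
  expect_error(to_spherical(c(0, 0, 0)), "no direction")
  expect_error(to_spherical(c(Inf, 0, 0)), "finite")
})

test_that("spherical transform inverts to 1e-12 on random vectors", {
  set.seed(11)
  a <- matrix(rnorm(3000), ncol = 3)
  for (conv in c("neg_z", "pos_z")) {
    p <- to_spherical(a, phi_convention = conv)
    back <- spherical_to_cartesian(p$rho, p$theta, p$phi, phi_convention = conv)
    expect_lt(max(abs(back - a)), 1e-12)
  }
})

test_that("UAS projection sets rho to one, keeps angles, and is idempotent", {
  p <- to_spherical(rbind(c(0, -2, 0), c(0.3, -0.4, 1.2)))
  u <- project_to_uas(p)
  expect_equal(u$rho, c(1, 1))
  expect_equal(u$theta, p$theta)
  expect_equal(u$phi, p$phi)
  expect_identical(project_to_uas(u), u)
  set.seed(5)
  big <- project_to_uas(to_spherical(matrix(rnorm(3e4), ncol = 3)))
  expect_true(all(big$rho == 1))
})

test_that("unit-norm invariant of projected window features", {
  rec <- generate_recording(day_cfg(2, hours = 1))
  ws <- extract_windows(rec)
  if (n_windows(ws) > 0) {
    nrm <- ws$features[, , "axs"]^2 + ws$features[, , "ays"]^2 +
      ws$features[, , "azs"]^2
    expect_lt(max(abs(nrm - 1)), 1e-9)
  }
})

test_that("bin indexing covers the corners and clamps the top edges", {
  expect_equal(bin_index(-pi / 2, -pi), list(i = 1L, j = 1L))
  expect_equal(bin_index(pi / 2, pi), list(i = 360L, j = 180L))
  expect_error(bin_index(2, 0), "theta")
  expect_error(bin_index(0, 4), "phi")
})

test_that("bin indexing matches a brute-force edge scan on random angles", {
  set.seed(21)
  n <- 1e5
  theta <- runif(n, -pi / 2, pi / 2)
  phi <- runif(n, -pi, pi)
  b <- bin_index(theta, phi)
  # oracle: find the bin by scanning the explicit edge vectors
  phi_edges <- seq(-pi, pi, length.out = 361)
  th_edges <- seq(-pi / 2, pi / 2, length.out = 181)
  i2 <- pmin(findInterval(phi, phi_edges, rightmost.closed = TRUE), 360L)
  j2 <- pmin(findInterval(theta, th_edges, rightmost.closed = TRUE), 180L)
  expect_identical(b$i, as.integer(i2))
  expect_identical(b$j, as.integer(j2))
  # partition property: every sample lands in exactly one valid bin
  expect_true(all(b$i >= 1 & b$i <= 360 & b$j >= 1 & b$j <= 180))
})

test_that("degenerate one-bin grids have the forced statistics", {
  g <- compute_bin_grid(const_rec(c(0, -1, 0), 50))
  expect_equal(sum(g$counts > 0), 1)
  expect_equal(max(g$prob), 1)
  expect_equal(g$mean_a[g$counts > 0], 1)
  expect_equal(g$sd_a[g$counts > 0], 0)
  # two samples, same bin, |a| = 0.9 and 1.1: forced mean/sd (population)
  g2 <- compute_bin_grid(make_rec(rbind(c(0, -0.9, 0), c(0, -1.1, 0))))
  expect_equal(g2$mean_a[g2$counts > 0], 1)
  expect_equal(g2$sd_a[g2$counts > 0], 0.1)
  expect_error(compute_bin_grid(make_rec(matrix(numeric(0), 0, 3))), "empty")
})

test_that("bin grid equals naive per-sample accumulation on random data", {
  set.seed(31)
  n <- 1e5
  accel <- matrix(rnorm(3 * n, sd = 0.6), ncol = 3)
  rec <- make_rec(accel)
  g <- compute_bin_grid(rec)
  o <- naive_bin_stats(accel)
  expect_identical(unname(g$counts), o$counts)
  expect_equal(g$mean_a, o$mean_a, tolerance = 1e-12)
  expect_equal(g$sd_a, o$sd_a, tolerance = 1e-9)
  expect_equal(sum(g$prob), 1, tolerance = 1e-12)
  expect_equal(sum(g$counts), n)
})

test_that("probability normalises to one for arbitrary recordings", {
  for (s in 1:3) {
    rec <- generate_recording(day_cfg(s, hours = 0.2))
    expect_equal(sum(compute_bin_grid(rec)$prob), 1, tolerance = 1e-12)
  }
})

test_that("|a| distribution is invariant under sensor-frame rotation", {
  set.seed(41)
  accel <- matrix(rnorm(300, sd = 0.8), ncol = 3)
  # random rotation via QR of a random matrix
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  r1 <- make_rec(accel)
  r2 <- make_rec(accel %*% q)
  expect_equal(sort(accel_magnitude(r1)), sort(accel_magnitude(r2)),
               tolerance = 1e-12)
})

test_that("hemisphere views place mass correctly and honour symmetry", {
  g <- compute_bin_grid(const_rec(c(0, -1, 0), 10))
  south <- hemisphere_view(g, "south", "prob")
  north <- hemisphere_view(g, "north", "prob")
  expect_equal(sum(!is.na(south$values)), 1)
  # the single hot cell is in the ring nearest the pole
  expect_true(!is.na(south$values[which(!is.na(south$values))]) &&
                which(!is.na(south$values)) <= 360)
  expect_equal(sum(!is.na(north$values)), 0)
  # mirrored grids give mirrored views
  set.seed(51)
  accel <- matrix(rnorm(3000, sd = 0.5), ncol = 3)
  gl <- compute_bin_grid(make_rec(accel))
  accel_m <- accel
  accel_m[, 1] <- -accel_m[, 1]
  gm <- compute_bin_grid(make_rec(accel_m))
  vl <- hemisphere_view(gl, "south", "prob")$values
  vm <- hemisphere_view(gm, "south", "prob")$values
  # phi -> -phi maps azimuth bin i to 361 - i
  expect_equal(unname(vl), unname(vm[360:1, , drop = FALSE]))
})

test_that("log-scaled probability view leaves empty bins missing", {
  g <- compute_bin_grid(const_rec(c(0, -1, 0), 10))
  lv <- hemisphere_view(g, "south", "prob", log_scale = TRUE)
  expect_equal(sum(is.finite(lv$values)), 1)
  expect_equal(lv$values[!is.na(lv$values)], 0)  # log10(prob 1)
  expect_error(hemisphere_view(g, "south", "mean", log_scale = TRUE),
               "probability")
})

test_that("bin grid text export round-trips", {
  rec <- generate_recording(day_cfg(3, hours = 0.05))
  g <- compute_bin_grid(rec)
  pre <- tempfile()
  write_bin_grid(g, pre)
  back <- read_bin_grid(pre)
  expect_equal(back$counts, unname(g$counts))
  expect_equal(back$mean_a, unname(g$mean_a), tolerance = 1e-12)
  expect_equal(back$n_total, g$n_total)
  unlink(paste0(pre, "_", c("counts", "prob", "mean_a", "sd_a"), ".csv"))
  unlink(paste0(pre, "_meta.json"))
})
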