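test_that("selection criteria validate their fields", {
  expect_s3_class(selection_criteria(), "selection_criteria")
  expect_error(selection_criteria(theta_max = 0.1))
  expect_error(selection_criteria(day_start = "20:00", day_end = "07:00"),
               "precede")
  expect_error(selection_criteria(sd_min = -1))
})

test_that("still standing yields an empty mask (rest carries no information)", {
  rec <- const_rec(c(0, -1, 0), 2000)
  mask <- select_samples(rec, compute_bin_grid(rec), selection_criteria())
  expect_false(any(mask))
})

test_that("elevation and daytime constraints exclude samples outright", {
  # sample at theta = -pi/6 fails the south-pole neighbourhood whatever its bin
  a <- c(0, -sin(pi / 6), cos(pi / 6))
  rec <- make_rec(matrix(rep(a, 100), ncol = 3, byrow = TRUE))
  g <- compute_bin_grid(rec)
  g$sd_a[] <- 1; g$mean_a[] <- 2  # force the bin filter to pass
  expect_false(any(select_samples(rec, g, selection_criteria())))
  # night-time samples are excluded even with passing bins
  rec_n <- const_rec(c(0, -1, 0), 100, start = "2021-06-07 02:00:00")
  g2 <- compute_bin_grid(rec_n)
  g2$sd_a[] <- 1; g2$mean_a[] <- 2
  expect_false(any(select_samples(rec_n, g2, selection_criteria())))
})

test_that("a planted active bout is recovered and rest excluded", {
  cfg <- profile_config(days = 4 / 24, start_clock = "2021-06-07 08:00:00",
                        seed = 5, gait_bout_rate_per_hour = c(0, 0, 0, 0),
                        high_g_event_rate = 0)
  rec <- generate_recording(cfg)  # pure rest
  mask0 <- select_samples(rec, compute_bin_grid(rec), selection_criteria())
  expect_equal(sum(mask0), 0)
  # one bout 10:00-10:05: plant by splicing a generated bout-only recording
  cfg2 <- profile_config(days = 4 / 24, start_clock = "2021-06-07 08:00:00",
                         seed = 5, bout_duration_s = 300,
                         gait_bout_rate_per_hour = c(0, 40, 0, 0),
                         bout_amp_weights = c(low = 0, medium = 1, high = 0),
                         high_g_event_rate = 0)
  rec2 <- generate_recording(cfg2)
  mask2 <- select_samples(rec2, compute_bin_grid(rec2), selection_criteria())
  expect_gt(sum(mask2), 0)
  # masked samples sit inside bouts: all have elevated variability
  tod <- time_of_day(rec2)
  expect_true(all(tod[mask2] >= 7 * 3600 & tod[mask2] < 20 * 3600))
})

test_that("tightening any criterion never grows the selection", {
  rec <- generate_recording(day_cfg(6, hours = 2))
  g <- compute_bin_grid(rec)
  base <- sum(select_samples(rec, g, selection_criteria()))
  tighter <- list(
    selection_criteria(sd_min = 0.05),
    selection_criteria(mean_dev_min = 0.05),
    selection_criteria(theta_max = -1.2),
    selection_criteria(day_start = "09:00", day_end = "18:00"))
  for (cr in tighter)
    expect_lte(sum(select_samples(rec, g, cr)), base)
  # OR rule is at least as permissive as AND
  expect_gte(sum(select_samples(rec, g, selection_criteria(combine_rule = "OR"))),
             base)
})

test_that("window segmentation floor-counts contiguous runs", {
  rec <- const_rec(c(0, -1, 0), 1500)
  mask <- rep(FALSE, 1500)
  mask[1:1000] <- TRUE      # 10 s at 100 Hz -> floor(1000/300) = 3
  ws <- segment_windows(rec, mask)
  expect_equal(n_windows(ws), 3)
  mask2 <- rep(FALSE, 1500)
  mask2[1:290] <- TRUE      # 2.9 s -> nothing
  expect_equal(n_windows(segment_windows(rec, mask2)), 0)
  # two runs: floor(650/300) + floor(400/300)
  mask3 <- rep(FALSE, 1500)
  mask3[1:650] <- TRUE
  mask3[1001:1400] <- TRUE
  expect_equal(n_windows(segment_windows(rec, mask3)), 3)
})

test_that("windows never span timestamp gaps or unmasked samples", {
  t <- (0:999) / 100
  t[501:1000] <- t[501:1000] + 5  # 5 s sensor-off gap
  rec <- imu_recording(t, matrix(rep(c(0, -1, 0), 1000), ncol = 3, byrow = TRUE),
                       sample_rate_hz = 100)
  ws <- segment_windows(rec, rep(TRUE, 1000))
  expect_equal(n_windows(ws), 2)  # floor(500/300) per side of the gap
  # every window's internal spacing is nominal
  expect_true(all(diff(ws$start_clock) > 0))
})

test_that("accept-all masking gives exactly sum of per-run floors", {
  set.seed(61)
  rec <- generate_recording(day_cfg(7, hours = 0.2))
  mask <- rep(TRUE, length(rec$time))
  ws <- segment_windows(rec, mask)
  expect_equal(n_windows(ws), length(rec$time) %/% 300)
  # against an independent floor-count oracle on a random speckled mask
  mask2 <- runif(length(rec$time)) < 0.95
  runs <- rle(mask2)
  oracle <- sum(runs$lengths[runs$values] %/% 300)
  expect_equal(n_windows(segment_windows(rec, mask2)), oracle)
})

test_that("window features carry the documented 12 channels", {
  rec <- generate_recording(day_cfg(8, hours = 0.1))
  ws <- segment_windows(rec, rep(TRUE, length(rec$time)))
  expect_equal(dim(ws$features)[2:3], c(300, 12))
  w1 <- ws$features[1, , ]
  expect_equal(w1[, "ra"], sqrt(w1[, "ax"]^2 + w1[, "ay"]^2 + w1[, "az"]^2))
  expect_equal(w1[, "axs"], w1[, "ax"] / w1[, "ra"])
  expect_equal(w1[, "theta"],
               atan2(w1[, "ay"], sqrt(w1[, "ax"]^2 + w1[, "az"]^2)))
})

test_that("train/validation split is a deterministic partition", {
  rec <- const_rec(c(0, -1, 0), 3300)
  ws <- segment_windows(rec, rep(TRUE, 3300), label = "healthy")
  expect_equal(n_windows(ws), 11)
  sp <- split_train_val(ws, 0.8, seed = 3)
  expect_equal(n_windows(sp$train), 8)
  expect_equal(n_windows(sp$val), 3)
  sp2 <- split_train_val(ws, 0.8, seed = 3)
  expect_identical(sp$train$start_clock, sp2$train$start_clock)
  # partition: every window in exactly one side
  all_starts <- sort(c(sp$train$start_clock, sp$val$start_clock))
  expect_identical(all_starts, sort(ws$start_clock))
  expect_error(split_train_val(ws, 1.2), "train_frac")
})

test_that("window archives round-trip with their criteria sidecar", {
  rec <- generate_recording(day_cfg(9, hours = 0.1))
  ws <- segment_windows(rec, rep(TRUE, length(rec$time)), label = "healthy")
  f <- tempfile(fileext = ".rds")
  crit <- selection_criteria(sd_min = 0.03)
  write_window_archive(ws, f, crit)
  back <- read_window_archive(f)
  expect_identical(back$features, ws$features)
  expect_identical(back$label, ws$label)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$sd_min, 0.03)
  unlink(c(f, paste0(f, ".json")))
})
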