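test_that("autocalibration recovers identity on well-calibrated data", {
  set.seed(21)
  seg <- generate_calibration_segment(noise_sd = 2)
  cal <- autocalibrate(seg)
  expect_true(cal$calibrated)
  expect_true(all(abs(cal$offset) < 1))
  expect_true(all(abs(cal$scale - 1) < 0.002))
  expect_lte(cal$error_after, cal$error_before)
})

test_that("autocalibration recovers an injected offset and scale", {
  off <- c(20, -15, 10); sc <- c(1.02, 0.98, 1.01)
  set.seed(22)
  seg <- generate_calibration_segment(
    orientations = rbind(diag(3), -diag(3),
                         c(1, 1, 0), c(0, 1, 1), c(1, 0, 1)),
    dwell_s = 30, noise_sd = 3, offset = off, scale = sc)
  cal <- autocalibrate(seg)
  expect_true(cal$calibrated)
  expect_true(all(abs(cal$offset - off) < 3))
  expect_true(all(abs(cal$scale - sc) < 0.005))
  # applying the fit makes stationary magnitudes land back on the 1 g sphere
  expect_lt(cal$error_after, 2)
})

test_that("segments without stationary windows fall back to identity with a flag", {
  set.seed(23)
  run <- generate_raw_segment(default_profiles()$running, duration_s = 120,
                              fs = 50)
  expect_warning(cal <- autocalibrate(run), "stationary")
  expect_false(cal$calibrated)
  expect_identical(unname(cal$offset), c(0, 0, 0))
  expect_identical(unname(cal$scale), c(1, 1, 1))
})

test_that("ENMO epoch values match hand computations", {
  # gravity only: ENMO is exactly zero
  n <- 100
  g_only <- raw_segment((0:(n - 1)) / 10, rep(0, n), rep(0, n), rep(1000, n))
  s <- compute_enmo_epochs(g_only)
  expect_true(all(s$values == 0))

  # Pythagorean magnitude 1300 -> 300 mg everywhere
  tri <- raw_segment((0:(n - 1)) / 10, rep(300, n), rep(400, n), rep(1200, n))
  expect_true(all(compute_enmo_epochs(tri)$values == 300))

  # alternating 1000/1400 along z: per-sample ENMO 0/400, epoch mean 200
  alt <- raw_segment((0:(n - 1)) / 10, rep(0, n), rep(0, n),
                     rep(c(1000, 1400), n / 2))
  expect_true(all(compute_enmo_epochs(alt)$values == 200))

  # empty segment -> empty series
  empty <- raw_segment(numeric(0), numeric(0), numeric(0), numeric(0))
  expect_length(compute_enmo_epochs(empty)$values, 0)
})

test_that("partial leading/trailing epochs are dropped, not padded", {
  # 12 s of 10 Hz data starting at t = 2 s: only epoch [5,10) is complete
  t <- seq(2, 13.9, by = 0.1)
  seg <- raw_segment(t, rep(0, length(t)), rep(0, length(t)),
                     rep(1200, length(t)))
  s <- compute_enmo_epochs(seg)
  expect_length(s$values, 1L)
  expect_equal(attr(s, "epoch_ids"), 1L)
})

test_that("ENMO epochs are rotation invariant", {
  set.seed(24)
  seg <- generate_raw_segment(default_profiles()$running, duration_s = 60,
                              fs = 50, orientation = c(0.2, -0.5, 0.84))
  # a fixed rotation about an arbitrary axis (orthogonal matrix)
  th <- 0.7; ax <- c(1, 2, 3) / sqrt(14)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  v <- as.matrix(seg[, c("x", "y", "z")]) %*% t(R)
  rot <- raw_segment(seg$time, v[, 1], v[, 2], v[, 3])
  a <- compute_enmo_epochs(seg)$values
  b <- compute_enmo_epochs(rot)$values
  expect_equal(b, a, tolerance = 1e-6)
})

test_that("epoch pipeline equals the naive per-sample reference exactly", {
  set.seed(25)
  for (rep_i in 1:5) {
    prof <- sample(default_profiles()[c("running", "walking", "cycling",
                                        "sedentary")], 1)[[1]]
    dur <- sample(c(17, 35, 60), 1)  # non-multiples of 5 exercise trailing drop
    seg <- generate_raw_segment(prof, duration_s = dur, fs = 20,
                                noise_sd = 5,
                                orientation = rnorm(3))
    cal <- identity_calibration()
    got <- compute_enmo_epochs(seg, cal)$values
    want <- ref_enmo_epochs(seg, cal)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("non-wear detection flags flatlines and spares movement", {
  profs <- default_profiles()
  # 2-h constant-orientation flatline: every epoch non-wear
  set.seed(26)
  flat <- generate_raw_segment(activity_profile("sedentary", 0, 0, 0),
                               duration_s = 7200, fs = 5, noise_sd = 1)
  expect_true(all(!detect_nonwear(flat)))

  # continuous running (movement on all axes): zero non-wear epochs
  run <- generate_raw_segment(profs$running, duration_s = 7200, fs = 5,
                              orientation = c(0.3, 0.5, 0.81), noise_sd = 8)
  expect_true(all(detect_nonwear(run)))

  # 24-h day with one 90-min flatline: flagged duration within one 15-min step
  day <- generate_raw_segment(profs$sedentary, duration_s = 86400, fs = 5,
                              noise_sd = 20)
  flat_start <- 10 * 3600 + 300     # 10:05, off the 15-min grid
  flat_idx <- day$time >= flat_start & day$time < flat_start + 90 * 60
  day$x[flat_idx] <- 600; day$y[flat_idx] <- 0; day$z[flat_idx] <- 800
  wear <- detect_nonwear(day)
  nonwear_min <- sum(!wear) * 5 / 60
  expect_lte(abs(nonwear_min - 90), 15)
})

test_that("valid-day filtering applies the 10-h rule with strict removal", {
  full <- make_series(rep(50, 17280))
  low <- make_series(rep(50, 17280),
                     wear = c(rep(TRUE, 7128), rep(FALSE, 17280 - 7128)))  # 9.9 h
  out <- filter_valid_days(list(full, low))
  expect_length(out$retained, 1L)
  expect_equal(out$wear_hours, c(24, 9.9))

  days <- c(replicate(39, full, simplify = FALSE), list(low))
  expect_equal(filter_valid_days(days)$retention, 39 / 40)

  # exactly 10 h is retained (strictly-below days are removed)
  boundary <- make_series(rep(50, 17280),
                          wear = c(rep(TRUE, 7200), rep(FALSE, 10080)))
  expect_length(filter_valid_days(list(boundary))$retained, 1L)

  # waking-window wear counting
  night_only <- make_series(rep(50, 17280),
                            wear = c(rep(TRUE, 4320), rep(FALSE, 12960)))
  expect_length(filter_valid_days(list(night_only),
                                  waking_window = c(6, 24))$retained, 0L)
})

test_that("calibration error never worsens and round-trips through JSON", {
  set.seed(27)
  for (i in 1:4) {
    seg <- generate_calibration_segment(
      dwell_s = 15, fs = 25, noise_sd = runif(1, 1, 8),
      offset = rnorm(3, 0, 15), scale = 1 + rnorm(3, 0, 0.02))
    cal <- suppressWarnings(autocalibrate(seg))
    expect_lte(cal$error_after, cal$error_before + 1e-9)
  }
  tmp <- tempfile(fileext = ".json")
  cal <- suppressWarnings(autocalibrate(generate_calibration_segment(noise_sd = 2)))
  write_calibration_json(cal, tmp)
  back <- read_calibration_json(tmp)
  expect_equal(back$offset, cal$offset, tolerance = 1e-12)
  expect_equal(back$scale, cal$scale, tolerance = 1e-12)
  expect_equal(back$calibrated, cal$calibrated)
})
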