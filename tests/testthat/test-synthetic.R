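test_that("cohort generation is byte-identical under a fixed seed", {
  cfg <- cohort_config(n_participants = 2, days_per_participant = 7, seed = 1)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$labels, b$labels)
  expect_identical(a$log, b$log)
  expect_identical(lapply(a$epochs, `[[`, "values"),
                   lapply(b$epochs, `[[`, "values"))
  expect_identical(lapply(a$epochs, `[[`, "wear"),
                   lapply(b$epochs, `[[`, "wear"))
})

test_that("degenerate category mixture yields all-rest days and an empty log", {
  cfg <- cohort_config(n_participants = 2, days_per_participant = 7,
                       category_probabilities = c(running = 0, rest = 1,
                                                  other_training = 0),
                       seed = 2)
  co <- generate_cohort(cfg, keep_epochs = FALSE)
  expect_true(all(co$labels$category == "rest"))
  expect_equal(nrow(co$log), 0L)
  expect_true(all(co$labels$training_load == 0))
})

test_that("invalid simplexes are rejected", {
  expect_error(cohort_config(category_probabilities = c(
    running = 0.5, rest = 0.5, other_training = 0.5)), "simplex")
  expect_error(cohort_config(other_activity_mix = c(cycling = 1)), "named")
  expect_error(cohort_config(log_noise = c(-0.1, 0, 0)), "non-negative")
})

test_that("empirical category fractions converge to the configured simplex", {
  cfg <- cohort_config(n_participants = 35, days_per_participant = 43,
                       category_probabilities = c(running = 0.46, rest = 0.43,
                                                  other_training = 0.11),
                       seed = 7)
  co <- generate_cohort(cfg, keep_epochs = FALSE)
  frac <- prop.table(table(co$labels$category))
  expect_equal(unname(frac[["running"]]), 0.46, tolerance = 0.03 / 0.46)
  expect_equal(unname(frac[["rest"]]), 0.43, tolerance = 0.03 / 0.43)
  expect_equal(unname(frac[["other_training"]]), 0.11, tolerance = 0.03 / 0.11)
})

test_that("ground-truth labels reflect the scheduled running sessions exactly", {
  co <- generate_cohort(small_cohort_config(seed = 11), keep_epochs = FALSE)
  for (k in seq_along(co$day_specs)) {
    spec <- co$day_specs[[k]]
    lab <- co$labels[k]
    run <- spec$sessions[is_running_activity(spec$sessions$activity), ]
    if (nrow(run) > 0) {
      expect_identical(lab$category, "running")
      expect_equal(lab$miles, sum(run$miles))
      expect_equal(lab$duration, sum(run$duration_min))
      expect_equal(lab$mean_rpe, mean(run$rpe))
      expect_equal(lab$training_load, mean(run$rpe) * sum(run$duration_min))
    } else {
      expect_true(lab$category %in% c("rest", "other_training"))
      expect_equal(lab$training_load, 0)
    }
  }
})

test_that("day epoch synthesis honours sessions, background and non-wear", {
  profs <- constant_profiles()
  # 40-min run with zero-variance profile: exactly 480 epochs at 760 mg
  spec <- make_spec(sessions = data.frame(
    activity = "running", start_min = 600, duration_min = 40))
  set.seed(3)
  s <- generate_day_epochs(spec, profs)
  expect_length(s$values, 17280)
  expect_identical(sum(s$values == 760), 480L)

  # rest day, zero-variance sedentary/sleep: nothing at or above 400 mg
  set.seed(3)
  rest <- generate_day_epochs(make_spec(), profs)
  expect_identical(sum(rest$values >= 400), 0L)

  # non-wear 02:00-04:00: exactly 1440 epochs masked, values zeroed
  spec_nw <- make_spec(nonwear = data.frame(start_min = 120, duration_min = 120))
  set.seed(3)
  nw <- generate_day_epochs(spec_nw, profs)
  expect_identical(sum(!nw$wear), 1440L)
  expect_true(all(nw$values[!nw$wear] == 0))

  expect_error(generate_day_epochs(make_spec(sessions = data.frame(
    activity = "juggling", start_min = 600, duration_min = 10)), profs),
    "unknown activity")
})

test_that("training-log corruption behaves as specified", {
  co <- generate_cohort(small_cohort_config(seed = 5), keep_epochs = FALSE)
  entries <- co$log
  # zero noise is the identity
  expect_equal(as.data.frame(corrupt_training_log(entries, c(0, 0, 0))),
               as.data.frame(entries))
  # omission probability one empties the log
  set.seed(1)
  expect_equal(nrow(corrupt_training_log(entries, c(1, 0, 0))), 0L)
  # retained count within the Binomial(1000, 0.9) 99% interval
  big <- entries[rep(seq_len(nrow(entries)), length.out = 1000)]
  set.seed(42)
  kept <- nrow(corrupt_training_log(big, c(0.1, 0, 0)))
  expect_gte(kept, qbinom(0.005, 1000, 0.9))
  expect_lte(kept, qbinom(0.995, 1000, 0.9))
  # rpe stays in 1..10 and miles stay non-negative under heavy noise
  set.seed(43)
  noisy <- corrupt_training_log(big, c(0, 1, 3))
  expect_true(all(noisy$rpe >= 1 & noisy$rpe <= 10))
  expect_true(all(noisy$miles >= 0, na.rm = TRUE))
})

test_that("raw segments carry gravity, sample counts and the target intensity", {
  profs <- default_profiles()
  # stationary sedentary signal: pure gravity, magnitude 1000 +/- 1 mg
  set.seed(8)
  still <- generate_raw_segment(activity_profile("sedentary", 0, 0, 0.6),
                                duration_s = 30, fs = 50,
                                orientation = c(1, 1, 1))
  vm <- sqrt(still$x^2 + still$y^2 + still$z^2)
  expect_true(all(abs(vm - 1000) <= 1))

  # exact sample count
  set.seed(8)
  seg <- generate_raw_segment(profs$running, duration_s = 5, fs = 100)
  expect_identical(nrow(seg), 500L)

  # independent per-sample ENMO recovers the profile mean
  set.seed(9)
  run <- generate_raw_segment(profs$running, duration_s = 300, fs = 100)
  ep <- ref_enmo_epochs(run)
  tol <- 2 * profs$running$epoch_sd / sqrt(length(ep))
  expect_lt(abs(mean(ep) - profs$running$epoch_mean), tol)
})

test_that("alternate-week monitoring calendar has the right shape", {
  d <- wristload:::monitoring_dates(as.Date("2016-01-04"), 43)
  expect_length(d, 43)
  expect_identical(d[1:7], as.Date("2016-01-04") + 0:6)
  expect_identical(d[8], as.Date("2016-01-04") + 14)  # skips a week
})
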