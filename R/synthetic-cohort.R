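#' Configuration for the synthetic running cohort
#'
#' Describes the cohort the generator emulates: experienced runners monitored
#' on alternate weeks, each calendar day being a running day, a rest day or
#' an other-training day (cycling, gym/exercise class, circuits, field or
#' racket sport, swim, other). Defaults mirror a cohort of 35 runners
#' contributing ~43 days each with day-category composition
#' running:rest:other close to 694:641:159 and ~2.5% of days failing the
#' 10-h wear filter.
#'
#' @param n_participants number of runners (> 0).
#' @param days_per_participant monitored days per runner (> 0).
#' @param category_probabilities named simplex over
#'   `c(running, rest, other_training)`; must sum to 1 within 1e-9.
#' @param other_activity_mix named simplex over the other-training activities
#'   (see [other_training_activities()]).
#' @param log_noise named vector `c(omission, miles_sd, rpe_sd)`: probability
#'   an entry is omitted from the written log, SD of the relative error on
#'   logged miles, SD of the jitter added to logged RPE. All >= 0; default is
#'   a faithful log.
#' @param pace_range per-participant running pace range, minutes per mile.
#' @param run_duration,other_duration `c(mean, sd, min, max)` minutes for
#'   running / other-training session durations (Normal, clamped).
#' @param double_run_prob probability a running day holds two runs.
#' @param session_shift_frac session-to-session intensity heterogeneity: each
#'   session's epoch mean is shifted by Normal(0, frac * profile SD). Ad-hoc
#'   cross-training is given twice this heterogeneity, reflecting the wider
#'   day-to-day variation of non-habitual activities.
#' @param pace_intensity_ref running intensity scales with participant pace:
#'   the running profile mean is multiplied by `pace_intensity_ref / pace`
#'   (faster runners hit higher wrist accelerations); set equal to the mean
#'   pace to centre the cohort on the profile anchor.
#' @param nonwear_bout_prob probability of a short (30-120 min) early-morning
#'   non-wear bout on an otherwise valid day.
#' @param invalid_day_prob probability a day has an 18-h non-wear bout and
#'   thus fails the 10-h wear filter (default 0.025, i.e. ~97.5% retention).
#' @param start_date first monitored date.
#' @param seed integer RNG seed; all generation is reproducible from it.
#'
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 35,
                          days_per_participant = 43,
                          category_probabilities = c(
                            running = 694, rest = 641, other_training = 159
                          ) / 1494,
                          other_activity_mix = c(
                            cycling = 0.30, gym = 0.28, circuits = 0.13,
                            field_racket = 0.11, swim = 0.10, other = 0.08
                          ),
                          log_noise = c(omission = 0, miles_sd = 0, rpe_sd = 0),
                          pace_range = c(9, 11),
                          run_duration = c(mean = 50, sd = 15, min = 20, max = 120),
                          other_duration = c(mean = 45, sd = 15, min = 20, max = 90),
                          double_run_prob = 0.10,
                          session_shift_frac = 0.3,
                          pace_intensity_ref = 10,
                          nonwear_bout_prob = 0.05,
                          invalid_day_prob = 0.025,
                          start_date = as.Date("2016-01-04"),
                          seed = 7L) {
  if (n_participants <= 0 || days_per_participant <= 0) {
    stop("participant and day counts must be > 0", call. = FALSE)
  }
  check_simplex(category_probabilities, c("running", "rest", "other_training"),
                "category_probabilities")
  check_simplex(other_activity_mix, other_training_activities(),
                "other_activity_mix")
  log_noise <- unlist(log_noise)
  if (length(log_noise) != 3L || any(log_noise < 0)) {
    stop("log_noise must be three non-negative values (omission, miles_sd, rpe_sd)",
         call. = FALSE)
  }
  names(log_noise) <- c("omission", "miles_sd", "rpe_sd")
  structure(
    list(n_participants = as.integer(n_participants),
         days_per_participant = as.integer(days_per_participant),
         category_probabilities = category_probabilities,
         other_activity_mix = other_activity_mix,
         log_noise = log_noise,
         pace_range = pace_range,
         run_duration = run_duration, other_duration = other_duration,
         double_run_prob = double_run_prob,
         session_shift_frac = session_shift_frac,
         pace_intensity_ref = pace_intensity_ref,
         nonwear_bout_prob = nonwear_bout_prob,
         invalid_day_prob = invalid_day_prob,
         start_date = as.Date(start_date),
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

check_simplex <- function(p, expected_names, what) {
  if (is.null(names(p)) || !setequal(names(p), expected_names)) {
    stop(what, " must be named over {", paste(expected_names, collapse = ", "),
         "}", call. = FALSE)
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop(what, " must be a probability simplex summing to 1", call. = FALSE)
  }
  invisible(TRUE)
}

run_surfaces <- function() c("road run", "off-road run", "track run", "treadmill run")

#' Map a training-log activity label to an intensity profile name
#'
#' All running surface types map to the single `running` profile; other
#' labels must name a profile directly.
#' @param activity character vector of activity labels.
#' @return character vector of profile names.
#' @export
activity_to_profile <- function(activity) {
  ifelse(is_running_activity(activity), "running", activity)
}

#' Generate a synthetic running cohort
#'
#' Draws, for each participant-day, a category (running / rest /
#' other-training), session schedule, non-wear bouts, a full-day 5-s ENMO
#' epoch series, a ground-truth day label and training-log entries. Log
#' entries are then passed through [corrupt_training_log()] with the
#' configured noise. Entirely reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param profiles named list of [activity_profile()]s covering every
#'   activity label used.
#' @param keep_epochs if `FALSE`, epoch series are dropped after day metrics
#'   would be computable (used by callers that stream days); the default
#'   keeps them.
#'
#' @return List with elements `config`, `day_specs` (list), `epochs` (list of
#'   [epoch_series()], or NULL), `labels` (ground-truth day labels,
#'   data.table), `log` (training-log entries, data.table), `profiles`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            profiles = default_profiles(),
                            keep_epochs = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  paces <- runif(config$n_participants, config$pace_range[1], config$pace_range[2])
  dates <- monitoring_dates(config$start_date, config$days_per_participant)

  specs <- list(); k <- 0L
  for (i in seq_along(ids)) {
    for (d in seq_along(dates)) {
      k <- k + 1L
      specs[[k]] <- generate_day_spec(ids[i], dates[d], config, paces[i])
    }
  }
  labels <- data.table::rbindlist(lapply(specs, spec_label))
  log <- data.table::rbindlist(lapply(specs, spec_log_entries))
  log <- corrupt_training_log(log, config$log_noise)

  epochs <- NULL
  if (keep_epochs) {
    epochs <- lapply(specs, generate_day_epochs, profiles = profiles)
  }
  list(config = config, day_specs = specs, epochs = epochs,
       labels = labels, log = log, profiles = profiles)
}

# Alternate-week monitoring calendar: 7-day blocks every other week.
monitoring_dates <- function(start_date, n_days) {
  blocks <- ceiling(n_days / 7)
  offs <- unlist(lapply(seq_len(blocks) - 1L, function(w) w * 14L + 0:6))
  start_date + offs[seq_len(n_days)]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

draw_duration <- function(par) {
  round(clamp(rnorm(1, par[["mean"]], par[["sd"]]), par[["min"]], par[["max"]]))
}

# One day's schedule: category, sessions (data.frame), non-wear bouts.
generate_day_spec <- function(participant_id, date, config, pace) {
  category <- sample(names(config$category_probabilities), 1L,
                     prob = config$category_probabilities)
  sessions <- empty_sessions()
  if (category == "running") {
    n_run <- 1L + rbinom(1L, 1L, config$double_run_prob)
    slots <- if (n_run == 1L) list(c(360, 1260)) else list(c(360, 750), c(780, 1260))
    for (s in seq_len(n_run)) {
      dur <- draw_duration(config$run_duration)
      start <- floor(runif(1, slots[[s]][1], slots[[s]][2] - dur))
      z <- rnorm(1)
      sessions <- rbind(sessions, data.frame(
        activity = sample(run_surfaces(), 1L, prob = c(.5, .2, .1, .2)),
        start_min = start, duration_min = dur,
        miles = round(dur / pace, 2),
        rpe = as.integer(clamp(round(1 + dur / 15 + 0.5 * z + rnorm(1, 0, 0.8)), 1, 10)),
        shift_z = z, shift_frac = config$session_shift_frac,
        intensity_mult = config$pace_intensity_ref / pace,
        stringsAsFactors = FALSE))
    }
  } else if (category == "other_training") {
    dur <- draw_duration(config$other_duration)
    start <- floor(runif(1, 360, 1260 - dur))
    sessions <- rbind(sessions, data.frame(
      activity = sample(names(config$other_activity_mix), 1L,
                        prob = config$other_activity_mix),
      start_min = start, duration_min = dur, miles = NA_real_,
      rpe = as.integer(clamp(round(1 + dur / 15 + rnorm(1)), 1, 10)),
      shift_z = rnorm(1), shift_frac = 2 * config$session_shift_frac,
      intensity_mult = 1, stringsAsFactors = FALSE))
  }
  nonwear <- data.frame(start_min = numeric(0), duration_min = numeric(0))
  u <- runif(1)
  if (u < config$invalid_day_prob) {
    nonwear <- data.frame(start_min = 120, duration_min = 1080)  # 02:00-20:00
  } else if (u < config$invalid_day_prob + config$nonwear_bout_prob) {
    dur <- round(runif(1, 30, 120))
    nonwear <- data.frame(start_min = floor(runif(1, 0, 360 - dur)),
                          duration_min = dur)
  }
  list(participant_id = participant_id, date = date, category = category,
       sessions = sessions, nonwear = nonwear,
       session_shift_frac = config$session_shift_frac)
}

empty_sessions <- function() {
  data.frame(activity = character(0), start_min = numeric(0),
             duration_min = numeric(0), miles = numeric(0),
             rpe = integer(0), shift_z = numeric(0), shift_frac = numeric(0),
             intensity_mult = numeric(0), stringsAsFactors = FALSE)
}

# Ground-truth day label derived directly from the scheduled sessions:
# any running session makes the day a running day; running miles/duration
# are summed, RPE averaged over running sessions, training load = mean RPE
# x summed running duration.
spec_label <- function(spec) {
  s <- spec$sessions
  run <- s[is_running_activity(s$activity), , drop = FALSE]
  other <- s[!is_running_activity(s$activity), , drop = FALSE]
  if (nrow(run) > 0L) {
    mean_rpe <- mean(run$rpe)
    dur <- sum(run$duration_min)
    data.table::data.table(
      participant_id = spec$participant_id, date = spec$date,
      category = "running",
      other_activities = paste(unique(other$activity), collapse = ";"),
      miles = sum(run$miles), duration = dur, mean_rpe = mean_rpe,
      training_load = mean_rpe * dur)
  } else {
    data.table::data.table(
      participant_id = spec$participant_id, date = spec$date,
      category = if (nrow(other) > 0L) "other_training" else "rest",
      other_activities = paste(unique(other$activity), collapse = ";"),
      miles = 0, duration = 0, mean_rpe = NA_real_, training_load = 0)
  }
}

min_to_hm <- function(m) sprintf("%02d:%02d", m %/% 60, m %% 60)

spec_log_entries <- function(spec) {
  s <- spec$sessions
  if (nrow(s) == 0L) {
    return(data.table::data.table(
      participant_id = character(0), date = as.Date(character(0)),
      start_time = character(0), end_time = character(0),
      activity = character(0), miles = numeric(0), rpe = integer(0)))
  }
  data.table::data.table(
    participant_id = spec$participant_id, date = spec$date,
    start_time = min_to_hm(s$start_min),
    end_time = min_to_hm(s$start_min + s$duration_min),
    activity = s$activity, miles = s$miles, rpe = s$rpe)
}

#' Generate one day's 5-s ENMO epoch series from a day specification
#'
#' Fills a full midnight-to-midnight day (17,280 epochs) with
#' background intensity by time of day (sleep before 06:30 and after 22:30,
#' sedentary otherwise), overwrites each session's window with draws from
#' that activity's profile (shifted by the session's intensity heterogeneity,
#' truncated at 0), and finally zeroes non-wear bouts in both values and
#' wear mask.
#'
#' @param spec a day specification as produced inside [generate_cohort()]:
#'   list with `participant_id`, `date`, `sessions` (data.frame with
#'   `activity`, `start_min`, `duration_min`, optional `shift_z`), `nonwear`
#'   (data.frame with `start_min`, `duration_min`), optional
#'   `session_shift_frac`.
#' @param profiles named profile list; every session activity must map to a
#'   profile via [activity_to_profile()].
#' @param epoch_s epoch length, seconds.
#' @return An [epoch_series()] of length 86400 / `epoch_s`.
#' @export
generate_day_epochs <- function(spec, profiles = default_profiles(),
                                epoch_s = 5) {
  n <- epochs_per_day(epoch_s)
  per_min <- 60 / epoch_s
  sleep <- profiles$sleep; sed <- profiles$sedentary
  values <- pmax(0, rnorm(n, sed$epoch_mean, sed$epoch_sd))
  sleep_idx <- c(seq_len(390 * per_min),                      # 00:00-06:30
                 (1350 * per_min + 1):n)                      # 22:30-24:00
  values[sleep_idx] <- pmax(0, rnorm(length(sleep_idx),
                                     sleep$epoch_mean, sleep$epoch_sd))
  default_frac <- spec$session_shift_frac
  if (is.null(default_frac)) default_frac <- 0
  s <- spec$sessions
  for (i in seq_len(nrow(s))) {
    pname <- activity_to_profile(s$activity[i])
    if (!pname %in% names(profiles)) {
      stop("unknown activity label: ", s$activity[i], call. = FALSE)
    }
    prof <- profiles[[pname]]
    shift_z <- if ("shift_z" %in% names(s)) s$shift_z[i] else 0
    frac <- if ("shift_frac" %in% names(s)) s$shift_frac[i] else default_frac
    mult <- if ("intensity_mult" %in% names(s)) s$intensity_mult[i] else 1
    idx <- session_epoch_idx(s$start_min[i], s$duration_min[i], per_min, n)
    values[idx] <- pmax(0, rnorm(length(idx),
                                 mult * prof$epoch_mean + frac * prof$epoch_sd * shift_z,
                                 prof$epoch_sd))
  }
  wear <- rep(TRUE, n)
  nw <- spec$nonwear
  for (i in seq_len(nrow(nw))) {
    idx <- session_epoch_idx(nw$start_min[i], nw$duration_min[i], per_min, n)
    values[idx] <- 0
    wear[idx] <- FALSE
  }
  epoch_series(spec$participant_id, spec$date, values, wear, epoch_s = epoch_s)
}

session_epoch_idx <- function(start_min, duration_min, per_min, n) {
  idx <- (start_min * per_min + 1):((start_min + duration_min) * per_min)
  idx[idx >= 1 & idx <= n]
}

#' Apply recall-style noise to training-log entries
#'
#' Each entry is independently omitted with probability
#' `log_noise["omission"]`; logged miles are multiplied by
#' `1 + Normal(0, miles_sd)` and floored at zero; logged RPE is jittered by
#' `Normal(0, rpe_sd)`, rounded, and clamped to 1..10. Uses the current RNG
#' state.
#'
#' @param entries training-log entries (data.frame with at least `miles` and
#'   `rpe` columns).
#' @param log_noise `c(omission, miles_sd, rpe_sd)`, all >= 0.
#' @return Entries of the same shape, possibly with fewer rows.
#' @export
corrupt_training_log <- function(entries,
                                 log_noise = c(omission = 0, miles_sd = 0,
                                               rpe_sd = 0)) {
  log_noise <- unlist(log_noise)
  if (any(log_noise < 0)) stop("log_noise parameters must be >= 0", call. = FALSE)
  out <- data.table::as.data.table(entries)
  n <- nrow(out)
  if (n == 0L) return(out)
  keep <- runif(n) >= log_noise[[1]]
  out <- out[keep]
  n <- nrow(out)
  if (n == 0L) return(out)
  if (log_noise[[2]] > 0) {
    out$miles <- pmax(0, out$miles * (1 + rnorm(n, 0, log_noise[[2]])))
  }
  if (log_noise[[3]] > 0) {
    out$rpe <- as.integer(clamp(round(out$rpe + rnorm(n, 0, log_noise[[3]])), 1, 10))
  }
  out
}

#' Simulate one regression cell with a designed population R-squared
#'
#' Draws `x ~ Normal(x_mean, x_sd)` and `y = intercept + slope * x + e` with
#' the noise SD chosen analytically so the population coefficient of
#' determination equals `r2`: `sd(e) = |slope| * x_sd * sqrt((1 - r2) / r2)`.
#' Rows are assigned round-robin to `n_participants` groups so the result
#' can exercise grouped cross-validation.
#'
#' @param n number of days.
#' @param r2 designed population R-squared, in (0, 1).
#' @param slope,intercept linear relation parameters.
#' @param x_mean,x_sd predictor distribution.
#' @param n_participants number of participant groups.
#' @return data.table with `participant_id`, `x`, `y`.
#' @export
simulate_validity_cell <- function(n, r2, slope = 0.15, intercept = 0.5,
                                   x_mean = 40, x_sd = 12,
                                   n_participants = 35) {
  stopifnot(r2 > 0, r2 < 1, n >= 3)
  noise_sd <- abs(slope) * x_sd * sqrt((1 - r2) / r2)
  x <- rnorm(n, x_mean, x_sd)
  y <- intercept + slope * x + rnorm(n, 0, noise_sd)
  data.table::data.table(
    participant_id = sprintf("P%02d", (seq_len(n) - 1L) %% n_participants + 1L),
    x = x, y = y)
}
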