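#' Raw triaxial acceleration segment
#'
#' One continuous wear bout of raw samples in milli-g. Timestamps are
#' seconds from the start of the segment's day (or segment), strictly
#' increasing; axis values are clipped by the device at +/- 8000 mg.
#'
#' @param time numeric timestamps, seconds, strictly increasing.
#' @param x,y,z per-axis acceleration, milli-g.
#' @return An object of class `raw_segment` (a data.frame).
#' @export
raw_segment <- function(time, x, y, z) {
  n <- length(time)
  if (length(x) != n || length(y) != n || length(z) != n) {
    stop("time, x, y, z must have equal length", call. = FALSE)
  }
  if (n > 1 && any(diff(time) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (n > 0 && max(abs(c(x, y, z))) > 8000 + 1e-9) {
    stop("axis values exceed the +/- 8000 mg device range", call. = FALSE)
  }
  structure(data.frame(time = time, x = x, y = y, z = z),
            class = c("raw_segment", "data.frame"))
}

#' @export
print.raw_segment <- function(x, ...) {
  cat(sprintf("<raw_segment> %d samples, %.1f s\n", nrow(x),
              if (nrow(x) > 1) diff(range(x$time)) else 0))
  invisible(x)
}

#' Read / write raw segments as CSV
#'
#' Columns: `timestamp` (seconds, fractional) or ISO-8601 with fractional
#' seconds, `x_mg`, `y_mg`, `z_mg`.
#' @param raw a [raw_segment()].
#' @param path CSV path.
#' @rdname raw_csv
#' @export
write_raw_csv <- function(raw, path) {
  data.table::fwrite(data.table::data.table(
    timestamp = raw$time, x_mg = raw$x, y_mg = raw$y, z_mg = raw$z), path)
  invisible(path)
}

#' @rdname raw_csv
#' @export
read_raw_csv <- function(path) {
  if (!file.exists(path)) stop("raw CSV not found: ", path, call. = FALSE)
  dt <- data.table::fread(path)
  need <- c("timestamp", "x_mg", "y_mg", "z_mg")
  if (!all(need %in% names(dt))) {
    stop("raw CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  ts <- dt$timestamp
  if (!is.numeric(ts)) {
    tt <- as.POSIXct(ts, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS")
    ts <- as.numeric(tt) - as.numeric(trunc(tt[1], "days"))
  }
  raw_segment(ts, dt$x_mg, dt$y_mg, dt$z_mg)
}

# ids of epochs fully covered by samples: an epoch is kept iff it holds the
# expected number of samples for the segment's (approximately uniform)
# sampling rate; partial first/last epochs drop out naturally.
full_epoch_ids <- function(time, epoch_s) {
  if (length(time) < 2L) return(integer(0))
  dt <- stats::median(diff(time))
  expected <- round(epoch_s / dt)
  ids <- floor(time / epoch_s + 1e-9)
  cnt <- table(ids)
  as.integer(names(cnt)[cnt >= expected])
}

#' Autocalibrate a raw segment against the 1 g sphere
#'
#' Estimates per-axis offset (mg) and scale (dimensionless) such that the
#' calibrated signal `offset + scale * x` has stationary-period vector
#' magnitude close to 1000 mg, by the standard iterative re-weighted
#' least-squares fit used in open-source accelerometer processing: stationary
#' 10-s windows (per-axis SD below `sd_crit`) supply mean vectors, each
#' iteration regresses their closest points on the 1 g sphere onto the raw
#' means, per axis.
#'
#' Requires at least `min_windows` stationary windows whose mean orientations
#' are pairwise separated by more than `min_angle_deg`; otherwise (or if the
#' fit fails to improve the error, or produces out-of-range scales) an
#' identity calibration is returned with `calibrated = FALSE` and a warning.
#'
#' @param raw a [raw_segment()].
#' @param window_s stationary window length, seconds.
#' @param sd_crit per-axis SD criterion for stationarity, mg.
#' @param min_windows minimum number of orientation-diverse windows.
#' @param min_angle_deg minimum pairwise angular separation, degrees.
#' @param max_iter,tol iteration controls.
#' @return A `calibration_params` object: `offset`, `scale`, `error_before`,
#'   `error_after` (mean absolute deviation of stationary magnitudes from
#'   1000 mg), `n_stationary`, `calibrated`.
#' @export
autocalibrate <- function(raw, window_s = 10, sd_crit = 13, min_windows = 3,
                          min_angle_deg = 15, max_iter = 200, tol = 1e-9) {
  M <- stationary_window_means(raw, window_s, sd_crit)
  if (nrow(M) < min_windows ||
      n_diverse_orientations(M, min_angle_deg) < min_windows) {
    warning("too few diverse stationary windows; returning identity calibration",
            call. = FALSE)
    err <- if (nrow(M)) mean(abs(sqrt(rowSums(M^2)) - 1000)) else NA_real_
    return(identity_calibration(err, nrow(M)))
  }
  offset <- c(0, 0, 0); scale <- c(1, 1, 1)
  error_before <- mean(abs(sqrt(rowSums(M^2)) - 1000))
  prev <- Inf
  for (it in seq_len(max_iter)) {
    cur <- sweep(sweep(M, 2, scale, "*"), 2, offset, "+")
    nrm <- sqrt(rowSums(cur^2))
    target <- cur * (1000 / nrm)
    for (a in 1:3) {
      fit <- stats::lm.fit(cbind(1, M[, a]), target[, a])
      offset[a] <- fit$coefficients[1]
      scale[a] <- fit$coefficients[2]
    }
    err <- mean(abs(nrm - 1000))
    if (abs(prev - err) < tol) break
    prev <- err
  }
  cur <- sweep(sweep(M, 2, scale, "*"), 2, offset, "+")
  error_after <- mean(abs(sqrt(rowSums(cur^2)) - 1000))
  if (any(scale <= 0.5 | scale >= 1.5) || error_after > error_before) {
    warning("autocalibration fit rejected (out-of-range scale or no improvement)",
            call. = FALSE)
    return(identity_calibration(error_before, nrow(M)))
  }
  structure(list(offset = setNames(offset, c("x", "y", "z")),
                 scale = setNames(scale, c("x", "y", "z")),
                 error_before = error_before, error_after = error_after,
                 n_stationary = nrow(M), calibrated = TRUE),
            class = "calibration_params")
}

identity_calibration <- function(error = NA_real_, n_stationary = 0L) {
  structure(list(offset = setNames(c(0, 0, 0), c("x", "y", "z")),
                 scale = setNames(c(1, 1, 1), c("x", "y", "z")),
                 error_before = error, error_after = error,
                 n_stationary = n_stationary, calibrated = FALSE),
            class = "calibration_params")
}

#' @export
print.calibration_params <- function(x, ...) {
  cat(sprintf(
    "<calibration_params> %s; offset (%.1f, %.1f, %.1f) mg; scale (%.4f, %.4f, %.4f); error %.2f -> %.2f mg (%d stationary windows)\n",
    if (x$calibrated) "fitted" else "identity",
    x$offset[1], x$offset[2], x$offset[3],
    x$scale[1], x$scale[2], x$scale[3],
    x$error_before, x$error_after, x$n_stationary))
  invisible(x)
}

#' Write / read calibration parameters as JSON
#' @param calibration a `calibration_params` object.
#' @param path JSON path.
#' @rdname calibration_json
#' @export
write_calibration_json <- function(calibration, path) {
  jsonlite::write_json(unclass(calibration), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(offset = setNames(as.numeric(x$offset), c("x", "y", "z")),
                 scale = setNames(as.numeric(x$scale), c("x", "y", "z")),
                 error_before = x$error_before, error_after = x$error_after,
                 n_stationary = x$n_stationary, calibrated = x$calibrated),
            class = "calibration_params")
}

stationary_window_means <- function(raw, window_s, sd_crit) {
  if (nrow(raw) < 2L) return(matrix(numeric(0), ncol = 3))
  ids <- floor(raw$time / window_s + 1e-9)
  dt <- stats::median(diff(raw$time))
  expected <- round(window_s / dt)
  sp <- split(seq_len(nrow(raw)), ids)
  keep <- vapply(sp, length, 0L) >= expected
  sp <- sp[keep]
  if (!length(sp)) return(matrix(numeric(0), ncol = 3))
  res <- vapply(sp, function(ix) {
    m <- cbind(raw$x[ix], raw$y[ix], raw$z[ix])
    c(apply(m, 2, stats::sd), colMeans(m))
  }, numeric(6))
  stat <- res[1, ] < sd_crit & res[2, ] < sd_crit & res[3, ] < sd_crit
  t(res[4:6, stat, drop = FALSE])
}

n_diverse_orientations <- function(M, min_angle_deg) {
  if (nrow(M) == 0L) return(0L)
  U <- M / sqrt(rowSums(M^2))
  sel <- 1L
  for (i in seq_len(nrow(U))[-1]) {
    cosang <- U[sel, , drop = FALSE] %*% U[i, ]
    if (all(cosang < cos(min_angle_deg * pi / 180))) sel <- c(sel, i)
  }
  length(sel)
}

#' Compute 5-s ENMO epochs from a raw segment
#'
#' Applies the calibration (`offset + scale * x`, per axis), computes
#' per-sample ENMO = max(0, vector magnitude - 1000) mg — truncation at zero
#' happens per sample, before epoch averaging — and averages within
#' `epoch_s`-second epochs aligned to the segment's time origin (midnight
#' when timestamps are seconds-of-day). Partial first/last epochs are
#' dropped, not padded.
#'
#' @param raw a [raw_segment()].
#' @param calibration a `calibration_params` or NULL for identity.
#' @param epoch_s epoch length, seconds.
#' @param participant_id,date identifiers for the resulting series.
#' @return An [epoch_series()]; empty segment gives an empty series. The
#'   epoch ids (0-based from the time origin) are attached as attribute
#'   `epoch_ids`.
#' @export
compute_enmo_epochs <- function(raw, calibration = NULL, epoch_s = 5,
                                participant_id = "unknown",
                                date = as.Date("2000-01-01")) {
  if (nrow(raw) == 0L) {
    return(epoch_series(participant_id, date, numeric(0), logical(0), epoch_s))
  }
  if (is.null(calibration)) calibration <- identity_calibration()
  v <- cbind(raw$x, raw$y, raw$z)
  v <- sweep(sweep(v, 2, calibration$scale, "*"), 2, calibration$offset, "+")
  enmo <- pmax(0, sqrt(rowSums(v^2)) - 1000)
  ids <- floor(raw$time / epoch_s + 1e-9)
  keep_ids <- full_epoch_ids(raw$time, epoch_s)
  sel <- ids %in% keep_ids
  if (!any(sel)) {
    return(epoch_series(participant_id, date, numeric(0), logical(0), epoch_s))
  }
  means <- vapply(split(enmo[sel], ids[sel]), mean, 0)
  out <- epoch_series(participant_id, date, as.numeric(means),
                      rep(TRUE, length(means)), epoch_s)
  attr(out, "epoch_ids") <- as.integer(names(means))
  out
}

#' Detect non-wear in a raw segment
#'
#' Evaluates 60-min windows every 15 min: a window whose per-axis SD is
#' below `sd_crit` and range below `range_crit` on at least `min_axes` axes
#' marks all epochs it overlaps as non-wear. The paper-style 10-h valid-day
#' filter operates on the resulting mask. Heuristic and thresholds follow
#' the published defaults of the open-source processing chain; the source
#' study does not state its non-wear algorithm.
#'
#' @param raw a [raw_segment()].
#' @param window_min,step_min window length and step, minutes.
#' @param sd_crit per-axis SD criterion, mg.
#' @param range_crit per-axis range criterion, mg.
#' @param min_axes number of axes that must look idle.
#' @param epoch_s epoch length the mask is reported on.
#' @return Logical wear mask (TRUE = worn) aligned with the epochs of
#'   [compute_enmo_epochs()] on the same segment.
#' @export
detect_nonwear <- function(raw, window_min = 60, step_min = 15, sd_crit = 13,
                           range_crit = 50, min_axes = 2, epoch_s = 5) {
  keep_ids <- full_epoch_ids(raw$time, epoch_s)
  wear <- rep(TRUE, length(keep_ids))
  if (nrow(raw) < 2L || !length(keep_ids)) return(wear)
  t0 <- raw$time[1]; t1 <- raw$time[nrow(raw)]
  dt <- stats::median(diff(raw$time))
  win_s <- window_min * 60; step_s <- step_min * 60
  # a window ending exactly at the last sample (+ one interval) still counts
  last_start <- t1 + dt - win_s
  if (last_start < t0) return(wear)
  starts <- seq(floor(t0 / step_s) * step_s, last_start, by = step_s)
  starts <- starts[starts >= t0 - step_s]
  for (s in starts) {
    i0 <- findInterval(s, raw$time, left.open = TRUE) + 1L
    i1 <- findInterval(s + win_s, raw$time)
    if (i1 - i0 < 2L) next
    m <- cbind(raw$x[i0:i1], raw$y[i0:i1], raw$z[i0:i1])
    idle <- apply(m, 2, stats::sd) < sd_crit &
      (apply(m, 2, max) - apply(m, 2, min)) < range_crit
    if (sum(idle) >= min_axes) {
      ep_lo <- floor(s / epoch_s)
      ep_hi <- ceiling((s + win_s) / epoch_s) - 1
      wear[keep_ids >= ep_lo & keep_ids <= ep_hi] <- FALSE
    }
  }
  wear
}

#' Filter days by minimum wear time
#'
#' Removes days with strictly less than `min_wear_h` hours of wear,
#' optionally counting wear only within a waking window (e.g. `c(6, 24)`),
#' and reports the retention fraction. Series are assumed to start at
#' midnight.
#'
#' @param days list of [epoch_series()].
#' @param min_wear_h minimum wear, hours (default 10).
#' @param waking_window optional `c(start_hour, end_hour)` restricting which
#'   epochs count as wear time; NULL counts the full 24-h day.
#' @return List with `retained` (list of series), `removed`, `retention`
#'   (fraction), `wear_hours` (numeric per input day).
#' @export
filter_valid_days <- function(days, min_wear_h = 10, waking_window = NULL) {
  wear_h <- vapply(days, function(s) {
    w <- s$wear
    if (!is.null(waking_window)) {
      hrs <- (seq_along(s$values) - 1) * s$epoch_s / 3600
      w <- w & hrs >= waking_window[1] & hrs < waking_window[2]
    }
    sum(w) * s$epoch_s / 3600
  }, 0)
  ok <- wear_h >= min_wear_h
  list(retained = days[ok], removed = days[!ok],
       retention = if (length(days)) mean(ok) else NA_real_,
       wear_hours = wear_h)
}
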