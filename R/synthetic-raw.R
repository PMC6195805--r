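#' Synthesise a raw triaxial acceleration segment for one activity
#'
#' Emulates the raw-signal regime of a wrist-worn research accelerometer
#' (default 100 Hz, clipped at +/- 8000 mg): a gravity component of 1000 mg
#' along `orientation` plus a dynamic component whose per-epoch mean follows
#' the activity profile. Within each 5-s epoch the dynamic part is
#' `e_k * (1 + sin(2 pi f t))` with `e_k` drawn from
#' `Normal(epoch_mean, epoch_sd)` truncated at 0, so it is non-negative and
#' — because profile frequencies are multiples of 0.2 Hz, giving an integer
#' number of cycles per epoch — averages exactly to `e_k` over the epoch.
#' An independent per-sample ENMO computation therefore recovers the
#' profile's epoch distribution.
#'
#' Sensor miscalibration can be injected via `offset`/`scale`: the returned
#' samples are `(true - offset) / scale` per axis, i.e. a device whose
#' readings need `offset + scale * x` to be correct.
#'
#' @param profile an [activity_profile()].
#' @param duration_s segment duration, seconds (> 0).
#' @param fs sampling frequency, Hz (> 0).
#' @param orientation 3-vector giving the gravity direction (normalised
#'   internally).
#' @param noise_sd per-axis white measurement noise SD, mg.
#' @param offset,scale injected calibration error (3-vectors).
#' @param epoch_s epoch length used for the dynamic component, seconds.
#' @return A [raw_segment()].
#' @export
generate_raw_segment <- function(profile, duration_s, fs = 100,
                                 orientation = c(0, 0, 1), noise_sd = 0,
                                 offset = c(0, 0, 0), scale = c(1, 1, 1),
                                 epoch_s = 5) {
  stopifnot(inherits(profile, "activity_profile"), duration_s > 0, fs > 0)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  n_ep <- ceiling(duration_s / epoch_s)
  e <- pmax(0, rnorm(n_ep, profile$epoch_mean, profile$epoch_sd))
  ep_idx <- pmin(floor(t / epoch_s) + 1L, n_ep)
  f <- profile$raw_frequency
  dyn <- if (f > 0) e[ep_idx] * (1 + sin(2 * pi * f * t)) else e[ep_idx]
  u <- orientation / sqrt(sum(orientation^2))
  v <- outer(1000 + dyn, u)
  if (noise_sd > 0) v <- v + matrix(rnorm(3 * n, 0, noise_sd), ncol = 3)
  v <- sweep(sweep(v, 2, offset, "-"), 2, scale, "/")
  v <- clamp(v, -8000, 8000)
  raw_segment(t, v[, 1], v[, 2], v[, 3])
}

#' Synthesise a stationary multi-orientation calibration segment
#'
#' Holds the sensor still in each supplied orientation for `dwell_s` seconds
#' (gravity only, magnitude 1000 mg, plus white noise), optionally injecting
#' a calibration error as in [generate_raw_segment()]. Used to exercise and
#' test autocalibration, which needs at least three stationary windows with
#' diverse orientations.
#'
#' @param orientations matrix with one orientation per row (default: the six
#'   axis-aligned orientations).
#' @param dwell_s seconds spent in each orientation.
#' @param fs sampling frequency, Hz.
#' @param noise_sd per-axis noise SD, mg (keep < 13 so windows register as
#'   stationary).
#' @param offset,scale injected calibration error.
#' @return A [raw_segment()].
#' @export
generate_calibration_segment <- function(orientations = rbind(diag(3), -diag(3)),
                                         dwell_s = 20, fs = 100, noise_sd = 3,
                                         offset = c(0, 0, 0),
                                         scale = c(1, 1, 1)) {
  stopifnot(ncol(orientations) == 3, dwell_s > 0, fs > 0)
  n_per <- round(dwell_s * fs)
  blocks <- lapply(seq_len(nrow(orientations)), function(i) {
    u <- orientations[i, ] / sqrt(sum(orientations[i, ]^2))
    matrix(1000 * u, nrow = n_per, ncol = 3, byrow = TRUE)
  })
  v <- do.call(rbind, blocks)
  n <- nrow(v)
  if (noise_sd > 0) v <- v + matrix(rnorm(3 * n, 0, noise_sd), ncol = 3)
  v <- sweep(sweep(v, 2, offset, "-"), 2, scale, "/")
  v <- clamp(v, -8000, 8000)
  raw_segment((seq_len(n) - 1L) / fs, v[, 1], v[, 2], v[, 3])
}
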