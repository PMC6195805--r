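#' Average acceleration over a day's wear time
#'
#' Mean 5-s epoch ENMO (mg) over the day's wear epochs — the standard
#' whole-day volume metric of habitual physical activity.
#'
#' @param series an [epoch_series()].
#' @return milli-g; `NA` (undefined, not zero) when the day has no wear
#'   epochs.
#' @export
average_acceleration <- function(series) {
  if (!any(series$wear)) return(NA_real_)
  mean(series$values[series$wear])
}

#' Most active 30 minutes
#'
#' Maximum, over all contiguous 30-min windows of the day consisting
#' entirely of wear epochs, of the window's mean ENMO (mg). Stride is one
#' epoch and windows do not wrap across midnight. High values reflect a
#' sustained bout — typically a deliberate training session — rather than
#' activity accumulated across the day.
#'
#' @param series an [epoch_series()].
#' @param window_min window length, minutes.
#' @return milli-g; `NA` when no all-wear window of the required length
#'   exists.
#' @export
most_active_30mins <- function(series, window_min = 30) {
  w <- as.integer(round(window_min * 60 / series$epoch_s))
  n <- length(series$values)
  if (n < w) return(NA_real_)
  cs <- cumsum(c(0, series$values))
  cw <- cumsum(c(0, as.numeric(series$wear)))
  sums <- cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
  wearcnt <- cw[(w + 1):(n + 1)] - cw[1:(n - w + 1)]
  ok <- wearcnt == w
  if (!any(ok)) return(NA_real_)
  max(sums[ok]) / w
}

#' Minutes at or above an intensity threshold
#'
#' Wear-time minutes per day with epoch ENMO at or above `threshold`
#' (inclusive). The default 400 mg is a published vigorous-intensity
#' threshold for wrist-worn accelerometry in adults.
#'
#' @param series an [epoch_series()].
#' @param threshold milli-g (default 400).
#' @return minutes.
#' @export
mins_above <- function(series, threshold = 400) {
  sum(series$wear & series$values >= threshold) * series$epoch_s / 60
}

#' Minutes accumulated in 50-mg intensity bins
#'
#' Assigns each wear epoch to a half-open bin `[lower, lower + width)` by
#' its ENMO value, between `lower_bound` and `upper_bound` mg (so the bins
#' are 50-99.99, 100-149.99, ... 3950-3999.99 by default), plus one overflow
#' bin for values at or above `upper_bound`. Activity below `lower_bound`
#' (50 mg) is considered non-meaningful and left uncounted.
#'
#' @param series an [epoch_series()].
#' @param lower_bound,upper_bound,width bin grid, mg.
#' @return Named numeric vector of minutes: one element per bin, named by
#'   its lower edge, plus `"overflow"`.
#' @export
intensity_bin_minutes <- function(series, lower_bound = 50,
                                  upper_bound = 4000, width = 50) {
  edges <- seq(lower_bound, upper_bound, by = width)
  v <- series$values[series$wear]
  idx <- findInterval(v, edges)   # 0 below floor, length(edges) = overflow
  cnt <- tabulate(idx, nbins = length(edges))
  mins <- cnt * series$epoch_s / 60
  names(mins) <- c(paste0("bin_", edges[-length(edges)]), "overflow")
  mins
}

#' Intensity-weighted workload from bin minutes
#'
#' The composite external-workload metric: sum over intensity bins with
#' lower edge in `[lower, upper)` of a representative bin intensity times
#' the minutes in that bin (units mg.min). The overflow bin is excluded —
#' time above 4000 mg is extremely brief and rare. The representative
#' intensity is the bin midpoint by default; the lower- and upper-edge
#' conventions are available since "intensity multiplied by duration" does
#' not fix the representative.
#'
#' @param bin_minutes output of [intensity_bin_minutes()].
#' @param lower,upper workload intensity bounds, mg.
#' @param representative one of `"midpoint"`, `"lower"`, `"upper"`.
#' @return milli-g minutes.
#' @export
workload <- function(bin_minutes, lower = 400, upper = 4000,
                     representative = c("midpoint", "lower", "upper")) {
  representative <- match.arg(representative)
  nm <- names(bin_minutes)
  bins <- grepl("^bin_", nm)
  edges <- as.numeric(sub("^bin_", "", nm[bins]))
  width <- if (length(edges) > 1) edges[2] - edges[1] else 50
  rep_val <- switch(representative,
                    midpoint = edges + width / 2,
                    lower = edges,
                    upper = edges + width)
  keep <- edges >= lower & edges < upper
  sum(rep_val[keep] * bin_minutes[bins][keep])
}

#' All daily accelerometer metrics for one epoch series
#'
#' @param series an [epoch_series()].
#' @param threshold threshold for [mins_above()], mg.
#' @param window_min window for [most_active_30mins()], minutes.
#' @param wl_lower,wl_upper,wl_representative workload parameters.
#' @return A `day_metrics` object: `participant_id`, `date`, `wear_h`,
#'   `avg_accel`, `most_active_30`, `mins_ge_400`, `wl_400_4000`,
#'   `bin_minutes`.
#' @export
day_metrics <- function(series, threshold = 400, window_min = 30,
                        wl_lower = 400, wl_upper = 4000,
                        wl_representative = "midpoint") {
  bins <- intensity_bin_minutes(series)
  structure(list(
    participant_id = series$participant_id,
    date = series$date,
    wear_h = sum(series$wear) * series$epoch_s / 3600,
    avg_accel = average_acceleration(series),
    most_active_30 = most_active_30mins(series, window_min),
    mins_ge_400 = mins_above(series, threshold),
    wl_400_4000 = workload(bins, wl_lower, wl_upper, wl_representative),
    bin_minutes = bins), class = "day_metrics")
}

#' @export
print.day_metrics <- function(x, ...) {
  cat(sprintf(
    "<day_metrics> %s %s: wear %.1f h, avg %.1f mg, MA30 %.1f mg, mins>=400 %.1f, WL %.0f mg.min\n",
    x$participant_id, format(x$date), x$wear_h, x$avg_accel,
    x$most_active_30, x$mins_ge_400, x$wl_400_4000))
  invisible(x)
}

#' Daily metrics table for a collection of days
#'
#' One row per participant-day with all scalar metrics and, optionally, the
#' intensity-bin minutes as `bin_*` columns.
#'
#' @param days list of [epoch_series()].
#' @param include_bins include the 80 bin columns (default TRUE).
#' @param ... passed to [day_metrics()].
#' @return A data.table.
#' @export
metrics_table <- function(days, include_bins = TRUE, ...) {
  rows <- lapply(days, function(s) {
    m <- day_metrics(s, ...)
    base <- data.table::data.table(
      participant_id = m$participant_id, date = m$date, wear_h = m$wear_h,
      avg_accel = m$avg_accel, most_active_30 = m$most_active_30,
      mins_ge_400 = m$mins_ge_400, wl_400_4000 = m$wl_400_4000)
    if (include_bins) base <- cbind(base, data.table::as.data.table(as.list(m$bin_minutes)))
    base
  })
  data.table::rbindlist(rows)
}

#' Write / read the daily metrics table as CSV
#' @param metrics a data.table from [metrics_table()].
#' @param path CSV path.
#' @rdname metrics_csv
#' @export
write_metrics_csv <- function(metrics, path) {
  out <- data.table::copy(metrics)
  out$date <- format(out$date)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname metrics_csv
#' @export
read_metrics_csv <- function(path) {
  if (!file.exists(path)) stop("metrics CSV not found: ", path, call. = FALSE)
  dt <- data.table::fread(path)
  dt$date <- as.Date(dt$date)
  dt
}
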