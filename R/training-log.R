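#' Is an activity label a running activity?
#'
#' Running on any surface counts: road, off-road, track and treadmill runs
#' (and the bare label "running" / "run"). Matching is case-insensitive.
#' @param activity character vector.
#' @return logical vector.
#' @export
is_running_activity <- function(activity) {
  tolower(trimws(activity)) %in%
    c("running", "run", "road run", "off-road run", "track run",
      "treadmill run")
}

parse_hm <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", trimws(x)))
  vapply(m, function(p) {
    if (length(p) != 3L) return(NA_real_)
    h <- as.numeric(p[2]); mi <- as.numeric(p[3])
    if (h > 23 || mi > 59) return(NA_real_)
    60 * h + mi
  }, 0)
}

#' Read and validate a training-log CSV
#'
#' Expected columns: `participant_id`, `date` (ISO-8601), `start_time`,
#' `end_time` (HH:MM clock times; session duration is derived in minutes),
#' `activity`, `miles` (blank/NA for non-running sessions), `rpe` (integer
#' 1-10, the session rating of perceived exertion). Malformed rows are
#' collected into a row-level problem report, never silently dropped:
#' with `strict = TRUE` (default) any problem aborts with a message naming
#' the offending rows; with `strict = FALSE` offending rows are removed and
#' the report is attached as attribute `"problems"`.
#'
#' Overnight sessions (end before start) are rejected rather than wrapped.
#'
#' @param path CSV path.
#' @param strict abort on any invalid row?
#' @return data.table with `participant_id`, `date`, `start_time`,
#'   `end_time`, `duration_min`, `activity`, `miles`, `rpe`.
#' @export
read_training_log <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("training log not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, colClasses = list(
    character = c("start_time", "end_time")))
  need <- c("participant_id", "date", "start_time", "end_time", "activity",
            "miles", "rpe")
  if (!all(need %in% names(dt))) {
    stop("training log must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(dt) == 0L) {
    return(data.table::data.table(
      participant_id = character(0), date = as.Date(character(0)),
      start_time = character(0), end_time = character(0),
      duration_min = numeric(0), activity = character(0),
      miles = numeric(0), rpe = integer(0)))
  }
  dates <- as.Date(as.character(dt$date), format = "%Y-%m-%d")
  s <- parse_hm(dt$start_time); e <- parse_hm(dt$end_time)
  miles <- suppressWarnings(as.numeric(dt$miles))
  rpe <- suppressWarnings(as.numeric(dt$rpe))
  problems <- data.table::rbindlist(list(
    prob(which(is.na(dates)), "unparseable date"),
    prob(which(is.na(s)), "unparseable start_time"),
    prob(which(is.na(e)), "unparseable end_time"),
    prob(which(!is.na(s) & !is.na(e) & e <= s), "end_time not after start_time"),
    prob(which(is.na(rpe) | rpe != round(rpe) | rpe < 1 | rpe > 10),
         "rpe outside 1-10"),
    prob(which(!is.na(miles) & miles < 0), "negative miles")))
  if (nrow(problems)) {
    data.table::setorder(problems, row)
    if (strict) {
      stop("invalid training-log rows: ",
           paste(sprintf("row %d (%s)", problems$row, problems$message),
                 collapse = "; "), call. = FALSE)
    }
  }
  out <- data.table::data.table(
    participant_id = as.character(dt$participant_id), date = dates,
    start_time = dt$start_time, end_time = dt$end_time,
    duration_min = e - s, activity = as.character(dt$activity),
    miles = miles, rpe = as.integer(rpe))
  bad <- unique(problems$row)
  if (length(bad)) out <- out[-bad]
  data.table::setattr(out, "problems", problems)
  out
}

prob <- function(rows, msg) {
  data.table::data.table(row = as.integer(rows),
                         message = rep(msg, length(rows)))
}

#' Write training-log entries as CSV
#' @param entries entries data.frame/data.table.
#' @param path CSV path.
#' @export
write_training_log <- function(entries, path) {
  out <- data.table::as.data.table(entries)
  out <- out[, c("participant_id", "date", "start_time", "end_time",
                 "activity", "miles", "rpe"), with = FALSE]
  out$date <- format(as.Date(out$date))
  data.table::fwrite(out, path)
  invisible(path)
}

#' Label calendar days from training-log entries
#'
#' Each calendar day in `calendar` is classified as a running day (any
#' running session on the day, regardless of other training), an
#' other-training day (sessions but none running), or a rest day (no
#' sessions). For running days, running miles and duration are summed over
#' running sessions, a mean running RPE is computed, and the session-RPE
#' training load is (re)calculated as mean RPE x summed running duration
#' (arbitrary units). Non-running sessions never feed the running criteria;
#' rest and other-training days carry zero miles, duration and training
#' load.
#'
#' @param entries validated entries from [read_training_log()] (or the
#'   generator), with a `duration_min` column or `start_time`/`end_time`.
#' @param calendar data.frame with `participant_id` and `date` listing every
#'   monitored day; days without entries become rest days.
#' @return data.table of day labels: `participant_id`, `date`, `category`,
#'   `other_activities`, `miles`, `duration`, `mean_rpe`, `training_load`.
#' @export
label_days <- function(entries, calendar) {
  cal <- data.table::as.data.table(calendar)[, .(participant_id, date)]
  cal <- unique(cal)
  cal$participant_id <- as.character(cal$participant_id)
  cal$date <- as.Date(cal$date)
  e <- data.table::as.data.table(entries)
  if (nrow(e) && !"duration_min" %in% names(e)) {
    e$duration_min <- parse_hm(e$end_time) - parse_hm(e$start_time)
  }
  if (nrow(e) == 0L) {
    lab <- cal
    lab[, `:=`(category = "rest", other_activities = "", miles = 0,
               duration = 0, mean_rpe = NA_real_, training_load = 0)]
    return(lab[])
  }
  e$participant_id <- as.character(e$participant_id)
  e$date <- as.Date(e$date)
  agg <- e[, {
    run <- is_running_activity(activity)
    if (any(run)) {
      dur <- sum(duration_min[run])
      mr <- mean(rpe[run])
      list(category = "running",
           other_activities = paste(unique(activity[!run]), collapse = ";"),
           miles = sum(miles[run], na.rm = TRUE), duration = dur,
           mean_rpe = mr, training_load = mr * dur)
    } else {
      list(category = "other_training",
           other_activities = paste(unique(activity), collapse = ";"),
           miles = 0, duration = 0, mean_rpe = NA_real_, training_load = 0)
    }
  }, by = .(participant_id, date)]
  lab <- merge(cal, agg, by = c("participant_id", "date"), all.x = TRUE)
  lab[is.na(category), `:=`(category = "rest", other_activities = "",
                            miles = 0, duration = 0, training_load = 0)]
  lab[]
}

#' Date-match day labels with accelerometer day metrics
#'
#' Inner join on participant-day. Accelerometer days without a label are
#' reported separately (candidate unlogged activity), as are labelled days
#' without accelerometer data (e.g. days failing the wear filter).
#' Duplicate participant-days on either side are an error.
#'
#' @param labels day labels (from [label_days()] or ground truth).
#' @param metrics daily metrics table (from [metrics_table()]).
#' @return List: `matched` (data.table), `unmatched_accelerometer`,
#'   `unmatched_log`, `counts`.
#' @export
match_days <- function(labels, metrics) {
  l <- data.table::as.data.table(labels)
  m <- data.table::as.data.table(metrics)
  l$participant_id <- as.character(l$participant_id)
  m$participant_id <- as.character(m$participant_id)
  l$date <- as.Date(l$date); m$date <- as.Date(m$date)
  for (nm in list(list(l, "labels"), list(m, "metrics"))) {
    dup <- duplicated(nm[[1]][, .(participant_id, date)])
    if (any(dup)) {
      stop("duplicate participant-day in ", nm[[2]], call. = FALSE)
    }
  }
  matched <- merge(m, l, by = c("participant_id", "date"))
  key_l <- paste(l$participant_id, l$date)
  key_m <- paste(m$participant_id, m$date)
  list(matched = matched,
       unmatched_accelerometer = m[!key_m %in% key_l],
       unmatched_log = l[!key_l %in% key_m],
       counts = c(labels = nrow(l), metrics = nrow(m),
                  matched = nrow(matched)))
}

#' Write day labels as CSV
#' @param labels labels data.table.
#' @param path CSV path.
#' @export
write_labels_csv <- function(labels, path) {
  out <- data.table::as.data.table(labels)
  out$date <- format(as.Date(out$date))
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read day labels from CSV
#' @param path CSV path.
#' @export
read_labels_csv <- function(path) {
  if (!file.exists(path)) stop("labels CSV not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, colClasses = list(character = "other_activities"))
  dt$date <- as.Date(dt$date)
  dt$participant_id <- as.character(dt$participant_id)
  dt
}
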