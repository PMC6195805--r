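#' ENMO epoch series for one participant-day
#'
#' The basic container downstream of raw-signal processing: a sequence of
#' 5-s mean ENMO values (milli-g) with a parallel wear mask. A full
#' midnight-to-midnight day at 5-s resolution has 17,280 epochs; shorter
#' series arise from partial wear bouts processed in isolation.
#'
#' @param participant_id participant identifier (coerced to character).
#' @param date calendar day (`Date` or ISO-8601 string).
#' @param values numeric vector of epoch ENMO means, milli-g, all >= 0.
#' @param wear logical wear mask, same length as `values`. Defaults to all
#'   worn.
#' @param epoch_s epoch length in seconds (default 5).
#'
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(participant_id, date, values, wear = NULL,
                         epoch_s = 5) {
  values <- as.numeric(values)
  if (anyNA(values) || any(values < 0)) {
    stop("epoch values must be non-negative and non-missing", call. = FALSE)
  }
  if (is.null(wear)) wear <- rep(TRUE, length(values))
  wear <- as.logical(wear)
  if (length(wear) != length(values)) {
    stop("wear mask must match values in length", call. = FALSE)
  }
  structure(
    list(participant_id = as.character(participant_id),
         date = as.Date(date), values = values, wear = wear,
         epoch_s = as.numeric(epoch_s)),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf(
    "<epoch_series> %s %s: %d x %gs epochs, %.1f h wear, mean ENMO %.1f mg\n",
    x$participant_id, format(x$date), length(x$values), x$epoch_s,
    sum(x$wear) * x$epoch_s / 3600,
    if (any(x$wear)) mean(x$values[x$wear]) else NA_real_))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$values)

epochs_per_day <- function(epoch_s = 5) as.integer(round(86400 / epoch_s))

#' Write / read epoch series as long-format CSV
#'
#' Columns: `participant_id`, `date` (ISO-8601), `epoch_index` (0-based from
#' midnight), `enmo_mg`, `wear` (0/1). `write_epoch_csv` accepts a single
#' series or a list; `read_epoch_csv` returns a list of `epoch_series`, one
#' per participant-day, ordered by epoch index.
#'
#' @param series an `epoch_series` or list of them.
#' @param path CSV file path.
#' @rdname epoch_csv
#' @return `read_epoch_csv`: list of `epoch_series`. `write_epoch_csv`:
#'   `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path) {
  if (inherits(series, "epoch_series")) series <- list(series)
  tabs <- lapply(series, function(s) {
    data.table::data.table(
      participant_id = s$participant_id,
      date = format(s$date),
      epoch_index = seq_along(s$values) - 1L,
      enmo_mg = s$values,
      wear = as.integer(s$wear))
  })
  data.table::fwrite(data.table::rbindlist(tabs), path)
  invisible(path)
}

#' @param epoch_s epoch length in seconds of the stored series.
#' @rdname epoch_csv
#' @export
read_epoch_csv <- function(path, epoch_s = 5) {
  if (!file.exists(path)) stop("epoch CSV not found: ", path, call. = FALSE)
  dt <- data.table::fread(path)
  need <- c("participant_id", "date", "epoch_index", "enmo_mg", "wear")
  if (!all(need %in% names(dt))) {
    stop("epoch CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  keys <- unique(dt[, .(participant_id, date)])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- dt[participant_id == keys$participant_id[i] & date == keys$date[i]]
    data.table::setorder(sub, epoch_index)
    out[[i]] <- epoch_series(keys$participant_id[i], keys$date[i],
                             sub$enmo_mg, sub$wear == 1L, epoch_s = epoch_s)
  }
  out
}
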