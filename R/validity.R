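#' Ordinary least-squares fit of a criterion on an accelerometer metric
#'
#' Simple linear regression of the training-log criterion (miles, duration
#' or training load) on an accelerometer predictor, with variance explained
#' R^2 = 1 - SS_res / SS_tot (unadjusted by default, matching the usual
#' "variance explained" reading; adjusted R^2 optionally).
#'
#' @param x predictor values (n >= 3, non-zero variance).
#' @param y criterion values.
#' @param adjusted also report adjusted R^2?
#' @return List: `slope`, `intercept`, `r2`, `n` (and `adj_r2` if requested).
#' @export
fit_validity <- function(x, y, adjusted = FALSE) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (var(x) == 0) stop("predictor has zero variance", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  out <- list(slope = unname(fit$coefficients[2]),
              intercept = unname(fit$coefficients[1]), r2 = r2, n = n)
  if (adjusted) {
    out$adj_r2 <- if (!is.na(r2)) 1 - (1 - r2) * (n - 1) / (n - 2) else NA_real_
  }
  out
}

#' Leave-one-participant-out cross-validated R^2
#'
#' Predicted-R^2 in pooled-PRESS form: for each participant, the regression
#' is fitted on all other participants' days and used to predict the
#' held-out days; then
#' `loocv_r2 = 1 - sum((y - yhat_heldout)^2) / sum((y - mean(y))^2)`
#' over all predicted days, with the global mean in the denominator. It can
#' be negative (the model predicts worse than the mean) but never exceeds
#' 1. Folds whose training predictor has zero variance are skipped with a
#' warning and excluded from both sums.
#'
#' @param data data.frame with a grouping column, predictor and criterion.
#' @param predictor,criterion column names.
#' @param group grouping column name (default `participant_id`).
#' @return List: `loocv_r2`, `n`, `n_folds`, `predictions` (data.table with
#'   per-day held-out predictions).
#' @export
loocv_r2 <- function(data, predictor, criterion, group = "participant_id") {
  data <- data.table::as.data.table(data)
  x <- data[[predictor]]; y <- data[[criterion]]
  g <- as.character(data[[group]])
  folds <- unique(g)
  if (length(folds) < 3L) stop("need >= 3 participants", call. = FALSE)
  pred <- rep(NA_real_, length(y))
  used <- rep(FALSE, length(y))
  n_folds <- 0L
  for (f in folds) {
    hold <- g == f
    xt <- x[!hold]; yt <- y[!hold]
    if (length(xt) < 3L || var(xt) == 0) {
      warning("fold ", f, " skipped: training predictor has zero variance",
              call. = FALSE)
      next
    }
    cf <- stats::lm.fit(cbind(1, xt), yt)$coefficients
    pred[hold] <- cf[1] + cf[2] * x[hold]
    used[hold] <- TRUE
    n_folds <- n_folds + 1L
  }
  if (!any(used)) stop("no evaluable folds", call. = FALSE)
  press <- sum((y[used] - pred[used])^2)
  ss_tot <- sum((y[used] - mean(y[used]))^2)
  list(loocv_r2 = 1 - press / ss_tot, n = sum(used), n_folds = n_folds,
       predictions = data.table::data.table(
         group = g[used], observed = y[used], predicted = pred[used]))
}

#' Convergent-validity matrix over classifiers, predictors and criteria
#'
#' For each classifier metric, the days predicted as running by its
#' cutpoint are selected (misclassified days legitimately enter, with their
#' logged criteria — a misclassified cycling day contributes 0 miles); on
#' those days each predictor x criterion combination is fitted by OLS with
#' leave-one-participant-out cross-validated R^2. With two classifiers, two
#' predictors and three criteria the primary matrix has 12 cells. A
#' secondary analysis on log-labelled running days is appended with
#' classifier `"training_log"` when `include_log_labelled`.
#'
#' @param matched matched participant-day table (from [match_days()]),
#'   containing the metric columns, `category` and criterion columns.
#' @param cutpoints named numeric vector: cutpoint per classifier metric.
#' @param predictors,criteria column names for the regression cells.
#' @param adjusted report adjusted R^2 instead of unadjusted?
#' @param include_log_labelled add the log-labelled secondary rows?
#' @param low_n_threshold cells with fewer selected days are flagged.
#' @return data.table: one row per cell with `classifier`, `predictor`,
#'   `criterion`, `n`, `slope`, `intercept`, `r2`, `loocv_r2`, `low_n`.
#' @export
validity_matrix <- function(matched, cutpoints,
                            predictors = c("mins_ge_400", "wl_400_4000"),
                            criteria = c("miles", "duration", "training_load"),
                            adjusted = FALSE,
                            include_log_labelled = TRUE,
                            low_n_threshold = 10) {
  matched <- data.table::as.data.table(matched)
  selections <- lapply(names(cutpoints), function(m) {
    matched[classify_days(matched[[m]], cutpoints[[m]])]
  })
  names(selections) <- names(cutpoints)
  if (include_log_labelled) {
    selections$training_log <- matched[category == "running"]
  }
  rows <- list()
  for (cl in names(selections)) {
    sub <- selections[[cl]]
    for (p in predictors) {
      for (cr in criteria) {
        n <- nrow(sub)
        if (n < 3L || var(sub[[p]]) == 0) {
          rows[[length(rows) + 1L]] <- data.table::data.table(
            classifier = cl, predictor = p, criterion = cr, n = n,
            slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
            loocv_r2 = NA_real_, low_n = TRUE)
          next
        }
        fit <- fit_validity(sub[[p]], sub[[cr]], adjusted = adjusted)
        cv <- tryCatch(suppressWarnings(loocv_r2(sub, p, cr)),
                       error = function(e) list(loocv_r2 = NA_real_))
        rows[[length(rows) + 1L]] <- data.table::data.table(
          classifier = cl, predictor = p, criterion = cr, n = n,
          slope = fit$slope, intercept = fit$intercept,
          r2 = if (adjusted) fit$adj_r2 else fit$r2,
          loocv_r2 = cv$loocv_r2, low_n = n < low_n_threshold)
      }
    }
  }
  data.table::rbindlist(rows)
}
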