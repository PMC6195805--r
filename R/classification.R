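#' Empirical ROC curve for a day-level metric
#'
#' Candidate thresholds are all distinct observed metric values (plus -Inf
#' and +Inf endpoints); a day is called running when its value is at or
#' above the threshold. The AUC is the trapezoidal area, computed exactly as
#' the Mann-Whitney statistic with ties credited 1/2: the probability that a
#' random running day's metric exceeds a random nonrunning day's.
#'
#' @param values numeric metric value per day.
#' @param labels logical (or 0/1) running indicator per day.
#' @return An object of class `roc_curve`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, plus the input `values`/`labels`.
#' @export
roc_curve <- function(values, labels) {
  labels <- as.logical(labels)
  stopifnot(length(values) == length(labels), !anyNA(values), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to fit a ROC curve", call. = FALSE)
  }
  thr <- c(-Inf, sort(unique(values)), Inf)
  sens <- vapply(thr, function(t) mean(values[labels] >= t), 0)
  spec <- vapply(thr, function(t) mean(values[!labels] < t), 0)
  r <- rank(values)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, values = values, labels = labels,
                 n_positive = n1, n_negative = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.3f (%d running vs %d nonrunning days)\n",
              x$auc, x$n_positive, x$n_negative))
  invisible(x)
}

#' Optimal classification cutpoint from a ROC curve
#'
#' Selects the threshold that optimises the balance between sensitivity and
#' specificity. The default rule maximises Youden's J = sensitivity +
#' specificity - 1 over all observed thresholds, breaking ties first by
#' minimal |sensitivity - specificity| and then by taking the lowest tied
#' threshold; the reported cutpoint is the midpoint between the optimal
#' threshold and the adjacent lower observed value, which places the
#' decision boundary between the two classes rather than on an observed
#' day. The alternative `"closest_topleft"` rule minimises the squared
#' distance to the (0, 1) ROC corner; the two rules can disagree.
#'
#' @param roc a [roc_curve()].
#' @param rule `"youden"` (default) or `"closest_topleft"`.
#' @return List of class `cutpoint_selection`: `cutpoint`, `threshold` (the
#'   observed optimal value), `sensitivity`, `specificity`, `youden_j`,
#'   `rule`, `uninformative`.
#' @export
optimal_cutpoint <- function(roc, rule = c("youden", "closest_topleft")) {
  rule <- match.arg(rule)
  stopifnot(inherits(roc, "roc_curve"))
  cand <- sort(unique(roc$values))
  sens <- vapply(cand, function(t) mean(roc$values[roc$labels] >= t), 0)
  spec <- vapply(cand, function(t) mean(roc$values[!roc$labels] < t), 0)
  j <- sens + spec - 1
  score <- if (rule == "youden") j else -((1 - sens)^2 + (1 - spec)^2)
  best <- which(score == max(score))
  if (length(best) > 1L) {
    bal <- abs(sens[best] - spec[best])
    best <- best[bal == min(bal)]
  }
  best <- best[1L]
  uninformative <- max(j) <= 0
  if (uninformative) {
    warning("no informative cutpoint: Youden's J <= 0 at every threshold",
            call. = FALSE)
  }
  t_star <- cand[best]
  lower <- if (best > 1L) cand[best - 1L] else t_star
  structure(list(cutpoint = (t_star + lower) / 2, threshold = t_star,
                 sensitivity = sens[best], specificity = spec[best],
                 youden_j = j[best], rule = rule,
                 uninformative = uninformative),
            class = "cutpoint_selection")
}

#' @export
print.cutpoint_selection <- function(x, ...) {
  cat(sprintf("<cutpoint_selection> cutpoint %.2f (%s): sens %.3f, spec %.3f, J %.3f\n",
              x$cutpoint, x$rule, x$sensitivity, x$specificity, x$youden_j))
  invisible(x)
}

#' Classify days with a cutpoint
#'
#' A day is classified as a running day when its metric value is at or
#' above the cutpoint (inclusive).
#'
#' @param values metric values.
#' @param cutpoint finite threshold.
#' @return logical predicted running indicator.
#' @export
classify_days <- function(values, cutpoint) {
  stopifnot(is.finite(cutpoint))
  values >= cutpoint
}

#' Accuracy breakdown of running-day predictions
#'
#' Computes sensitivity (running days classified as running) and specificity
#' (nonrunning days classified as nonrunning) as percentages, breaks the
#' nonrunning side down into rest and other-training days, and reports the
#' per-activity misclassification percentage: of the other-training days on
#' which an activity occurs, the percentage predicted as running. Activities
#' with zero occurrences are omitted, not reported as 0/0.
#'
#' @param predicted logical predicted running indicator.
#' @param labels data.frame with `category` (running / other_training /
#'   rest) and optionally `other_activities` (";"-separated labels).
#' @return List: confusion counts, percentage fields, and
#'   `misclassification` (data.table `activity`, `n_occurrences`,
#'   `n_misclassified`, `pct_misclassified`).
#' @export
accuracy_breakdown <- function(predicted, labels) {
  labels <- data.table::as.data.table(labels)
  stopifnot(length(predicted) == nrow(labels))
  is_run <- labels$category == "running"
  tp <- sum(predicted & is_run); fn <- sum(!predicted & is_run)
  fp <- sum(predicted & !is_run); tn <- sum(!predicted & !is_run)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  rest <- labels$category == "rest"
  other <- labels$category == "other_training"
  mis <- data.table::data.table(activity = character(0),
                                n_occurrences = integer(0),
                                n_misclassified = integer(0),
                                pct_misclassified = numeric(0))
  if ("other_activities" %in% names(labels) && any(other)) {
    acts <- strsplit(labels$other_activities[other], ";", fixed = TRUE)
    pred_o <- predicted[other]
    tab <- data.table::rbindlist(lapply(seq_along(acts), function(i) {
      a <- setdiff(acts[[i]], "")
      if (!length(a)) return(NULL)
      data.table::data.table(activity = a, mis = pred_o[i])
    }))
    if (nrow(tab)) {
      mis <- tab[, .(n_occurrences = .N, n_misclassified = sum(mis),
                     pct_misclassified = 100 * mean(mis)), by = activity]
      data.table::setorder(mis, -pct_misclassified)
    }
  }
  list(n = length(predicted),
       tp = tp, fn = fn, fp = fp, tn = tn,
       accuracy = (tp + tn) / length(predicted),
       pct_running_correct = pct(tp, tp + fn),
       pct_nonrunning_correct = pct(tn, fp + tn),
       pct_rest_correct = pct(sum(!predicted & rest), sum(rest)),
       pct_other_training_correct = pct(sum(!predicted & other), sum(other)),
       misclassification = mis)
}

#' Fit and evaluate an optimal cutpoint for one metric
#'
#' Convenience wrapper: ROC curve, optimal cutpoint, in-sample
#' classification and full accuracy breakdown for one accelerometer metric
#' against the day labels.
#'
#' @param data data.frame with the metric column and `category` (plus
#'   optional `other_activities`).
#' @param metric name of the metric column.
#' @param rule cutpoint rule, see [optimal_cutpoint()].
#' @return Object of class `cutpoint_result`.
#' @export
fit_cutpoint <- function(data, metric, rule = "youden") {
  data <- data.table::as.data.table(data)
  values <- data[[metric]]
  labels <- data$category == "running"
  roc <- roc_curve(values, labels)
  sel <- optimal_cutpoint(roc, rule)
  predicted <- classify_days(values, sel$cutpoint)
  br <- accuracy_breakdown(predicted, data)
  structure(c(list(metric_name = metric, cutpoint = sel$cutpoint,
                   auc = roc$auc, rule = rule, roc = roc, selection = sel,
                   predicted = predicted), br),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("<cutpoint_result> %s: cutpoint %.1f, AUC %.3f\n",
              x$metric_name, x$cutpoint, x$auc))
  cat(sprintf("  running correct %.1f%%, nonrunning correct %.1f%% (rest %.1f%%, other training %.1f%%)\n",
              x$pct_running_correct, x$pct_nonrunning_correct,
              x$pct_rest_correct, x$pct_other_training_correct))
  if (nrow(x$misclassification)) {
    cat("  other-training misclassified as running:\n")
    for (i in seq_len(nrow(x$misclassification))) {
      cat(sprintf("    %-13s %5.1f%% (%d/%d)\n",
                  x$misclassification$activity[i],
                  x$misclassification$pct_misclassified[i],
                  x$misclassification$n_misclassified[i],
                  x$misclassification$n_occurrences[i]))
    }
  }
  invisible(x)
}

#' Leave-one-out cross-validation of the cutpoint classifier
#'
#' Default unit is the participant (respecting the clustering of days
#' within runner): for each fold the ROC cutpoint is fitted on all other
#' participants' days and evaluated on the held-out participant's days.
#' Held-out AUC is computed only when the held-out fold contains both
#' classes (otherwise the fold is flagged and contributes accuracy only).
#' Folds whose training set is single-class are skipped with a warning.
#' Per-day LOOCV is available via `unit = "day"`.
#'
#' @param data data.frame with `participant_id`, the metric column and
#'   `category`.
#' @param metric metric column name.
#' @param rule cutpoint rule.
#' @param unit `"participant"` (default) or `"day"`.
#' @return Object of class `cv_result`: `folds` (data.table) and `summary`
#'   (pooled held-out accuracy, mean/min held-out AUC over evaluable folds,
#'   full-data AUC and cutpoint).
#' @export
loocv_classification <- function(data, metric, rule = "youden",
                                 unit = c("participant", "day")) {
  unit <- match.arg(unit)
  data <- data.table::as.data.table(data)
  values <- data[[metric]]
  is_run <- data$category == "running"
  fold_of <- if (unit == "participant") as.character(data$participant_id)
             else as.character(seq_len(nrow(data)))
  fold_ids <- unique(fold_of)
  if (length(fold_ids) < 3L) stop("need >= 3 folds", call. = FALSE)
  rows <- vector("list", length(fold_ids))
  correct_total <- 0L; n_total <- 0L
  for (i in seq_along(fold_ids)) {
    hold <- fold_of == fold_ids[i]
    tr_v <- values[!hold]; tr_y <- is_run[!hold]
    if (length(unique(tr_y)) < 2L) {
      warning("training fold single-class; fold ", fold_ids[i], " skipped",
              call. = FALSE)
      next
    }
    sel <- suppressWarnings(optimal_cutpoint(roc_curve(tr_v, tr_y), rule))
    pred <- classify_days(values[hold], sel$cutpoint)
    acc <- mean(pred == is_run[hold])
    both <- length(unique(is_run[hold])) == 2L
    auc <- if (both) roc_curve(values[hold], is_run[hold])$auc else NA_real_
    correct_total <- correct_total + sum(pred == is_run[hold])
    n_total <- n_total + sum(hold)
    rows[[i]] <- data.table::data.table(
      fold_id = fold_ids[i], n_days = sum(hold), cutpoint = sel$cutpoint,
      accuracy = acc, auc = auc, both_classes = both)
  }
  folds <- data.table::rbindlist(rows)
  if (nrow(folds) == 0L) stop("no evaluable folds", call. = FALSE)
  full <- fit_cutpoint(data, metric, rule)
  eval_auc <- folds$auc[folds$both_classes]
  structure(list(
    folds = folds, metric_name = metric, unit = unit,
    summary = list(
      n_folds = nrow(folds),
      pooled_accuracy = correct_total / n_total,
      mean_fold_accuracy = mean(folds$accuracy),
      mean_auc = if (length(eval_auc)) mean(eval_auc) else NA_real_,
      min_auc = if (length(eval_auc)) min(eval_auc) else NA_real_,
      full_auc = full$auc, full_cutpoint = full$cutpoint)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<cv_result> %s, %d %s folds: pooled held-out accuracy %.3f; held-out AUC mean %.3f, min %.3f (full-data AUC %.3f, cutpoint %.1f)\n",
    x$metric_name, s$n_folds, x$unit, s$pooled_accuracy, s$mean_auc,
    s$min_auc, s$full_auc, s$full_cutpoint))
  invisible(x)
}

#' Sample size for detecting an AUROC above a null value
#'
#' Hanley-McNeil approximation with the negative-exponential variance
#' kernel: for an AUROC theta, Q1 = theta / (2 - theta),
#' Q2 = 2 theta^2 / (1 + theta), and the equal-group large-n variance
#' kernel is V(theta) = Q1 + Q2 - 2 theta^2. The number of positive days is
#'
#'   n = ceiling( (z_{1-alpha/2} sqrt(V(auc_null)) +
#'                 z_{power} sqrt(V(auc_alt)))^2 / (auc_alt - auc_null)^2 )
#'
#' and the total is n * (1 + ratio) with `ratio` negatives per positive.
#' With the defaults (alternative 0.6 against a null of 0.5, two-sided
#' alpha 0.05, power 0.80, 1:1 allocation) this gives 129 positive days and
#' 258 in total.
#'
#' @param auc_alt alternative AUROC, in (auc_null, 1).
#' @param auc_null null AUROC, in \[0.5, auc_alt).
#' @param alpha two-sided type-I error rate.
#' @param power target power.
#' @param ratio negative:positive allocation ratio.
#' @return List of class `auroc_n`: `n_per_group` (positive days),
#'   `n_negative`, `n_total`.
#' @export
auroc_sample_size <- function(auc_alt, auc_null = 0.5, alpha = 0.05,
                              power = 0.80, ratio = 1) {
  if (!(auc_null >= 0.5 && auc_null < auc_alt && auc_alt < 1)) {
    stop("need 0.5 <= auc_null < auc_alt < 1", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1 || ratio <= 0) {
    stop("alpha and power must be in (0,1), ratio > 0", call. = FALSE)
  }
  vkernel <- function(theta) {
    q1 <- theta / (2 - theta)
    q2 <- 2 * theta^2 / (1 + theta)
    q1 + q2 - 2 * theta^2
  }
  za <- qnorm(1 - alpha / 2); zb <- qnorm(power)
  n <- ceiling((za * sqrt(vkernel(auc_null)) + zb * sqrt(vkernel(auc_alt)))^2 /
                 (auc_alt - auc_null)^2)
  structure(list(n_per_group = as.integer(n),
                 n_negative = as.integer(ceiling(n * ratio)),
                 n_total = as.integer(n + ceiling(n * ratio))),
            class = "auroc_n")
}

#' @export
print.auroc_n <- function(x, ...) {
  cat(sprintf("<auroc_n> %d positive + %d negative days (total %d)\n",
              x$n_per_group, x$n_negative, x$n_total))
  invisible(x)
}
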