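#' Study configuration
#'
#' All analysis parameters in one seedable object. Every place where field
#' practice leaves a genuine choice (cutpoint rule, cross-validation unit,
#' workload representative intensity, waking window for the wear filter) is
#' a configuration key, so sensitivity to those choices is one flag away.
#'
#' @param seed study-level seed; overrides the cohort config's seed.
#' @param cohort a [cohort_config()] for the synthetic cohort.
#' @param min_wear_h valid-day wear threshold, hours.
#' @param waking_window optional `c(start_hour, end_hour)` for wear counting.
#' @param threshold vigorous-intensity threshold, mg.
#' @param window_min most-active window, minutes.
#' @param wl_lower,wl_upper,wl_representative workload parameters.
#' @param cutpoint_rule `"youden"` or `"closest_topleft"`.
#' @param cv_unit `"participant"` or `"day"`.
#' @param class_metrics metrics entered into ROC classification.
#' @param validity_classifiers metrics whose cutpoints select running days
#'   for the validity regressions.
#' @param predictors,criteria validity-matrix axes.
#' @param output_dir where to persist intermediates and the report (NULL:
#'   in-memory only).
#' @param persist_epochs also write the (large) long-format epoch CSV?
#' @return List of class `study_config`.
#' @export
study_config <- function(seed = 7L,
                         cohort = cohort_config(seed = seed),
                         min_wear_h = 10, waking_window = NULL,
                         threshold = 400, window_min = 30,
                         wl_lower = 400, wl_upper = 4000,
                         wl_representative = "midpoint",
                         cutpoint_rule = "youden",
                         cv_unit = "participant",
                         class_metrics = c("avg_accel", "most_active_30",
                                           "mins_ge_400"),
                         validity_classifiers = c("mins_ge_400",
                                                  "most_active_30"),
                         predictors = c("mins_ge_400", "wl_400_4000"),
                         criteria = c("miles", "duration", "training_load"),
                         output_dir = NULL, persist_epochs = FALSE) {
  cohort$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), cohort = cohort,
                 min_wear_h = min_wear_h, waking_window = waking_window,
                 threshold = threshold, window_min = window_min,
                 wl_lower = wl_lower, wl_upper = wl_upper,
                 wl_representative = wl_representative,
                 cutpoint_rule = cutpoint_rule, cv_unit = cv_unit,
                 class_metrics = class_metrics,
                 validity_classifiers = validity_classifiers,
                 predictors = predictors, criteria = criteria,
                 output_dir = output_dir, persist_epochs = persist_epochs),
            class = "study_config")
}

#' Load a study configuration from JSON
#'
#' Reads a (possibly partial) JSON configuration and merges it over the
#' defaults of [study_config()] / [cohort_config()]. Unknown keys are an
#' error.
#'
#' @param path JSON file.
#' @param seed optional seed overriding the file's.
#' @return A `study_config`.
#' @export
read_study_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_keys <- names(formals(cohort_config))
  study_keys <- setdiff(names(formals(study_config)), "cohort")
  unknown <- setdiff(names(raw), c(study_keys, "cohort"))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cargs <- raw$cohort
  if (!is.null(cargs)) {
    bad <- setdiff(names(cargs), cohort_keys)
    if (length(bad)) stop("unknown cohort keys: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    for (k in intersect(names(cargs),
                        c("category_probabilities", "other_activity_mix",
                          "log_noise", "run_duration", "other_duration"))) {
      cargs[[k]] <- unlist(cargs[[k]])
    }
  }
  cohort <- do.call(cohort_config, as.list(cargs))
  sargs <- raw[setdiff(names(raw), "cohort")]
  sargs$cohort <- cohort
  if (!is.null(seed)) sargs$seed <- seed
  do.call(study_config, sargs)
}

# small stable content hash (FNV-1a, 32-bit arithmetic in doubles) used for
# report provenance; not cryptographic.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) + (h %/% 2^31) * 2^31
    h <- (h * 16777619) %% 2^32
  }
  paste0(format(as.hexmode(as.integer(h %% 2^31)), width = 8),
         as.integer(h %/% 2^31))
}

config_hash <- function(config) {
  fnv1a(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE))
}

stage <- function(name, verbose, expr) {
  if (verbose) message("[", name, "] ...")
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full simulate-process-classify-validate study
#'
#' Orchestrates the whole pipeline on a synthetic cohort: generate the
#' cohort, apply the wear-time valid-day filter, compute daily metrics,
#' label days from the training log, date-match, fit and cross-validate
#' ROC cutpoints for each classification metric, and fill the convergent
#' validity matrix. Deterministic given the config seed.
#'
#' @param config a [study_config()].
#' @param verbose log stage progress?
#' @return Object of class `study_report`: cohort summary, cutpoint table,
#'   misclassification table, validity matrix, CV summaries, provenance.
#' @export
run_study <- function(config = study_config(), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  cohort <- stage("simulate", verbose, generate_cohort(config$cohort))
  filt <- stage("wear_filter", verbose,
                filter_valid_days(cohort$epochs, config$min_wear_h,
                                  config$waking_window))
  metrics <- stage("metrics", verbose, metrics_table(
    filt$retained, threshold = config$threshold,
    window_min = config$window_min, wl_lower = config$wl_lower,
    wl_upper = config$wl_upper, wl_representative = config$wl_representative))
  calendar <- unique(data.table::rbindlist(lapply(
    cohort$day_specs, function(s) data.table::data.table(
      participant_id = s$participant_id, date = s$date))))
  labels <- stage("label", verbose, label_days(cohort$log, calendar))
  md <- stage("match", verbose, match_days(labels, metrics))
  matched <- md$matched

  class_fits <- list(); cv_fits <- list()
  stage("classify", verbose, {
    for (m in config$class_metrics) {
      class_fits[[m]] <- fit_cutpoint(matched, m, config$cutpoint_rule)
      cv_fits[[m]] <- suppressWarnings(
        loocv_classification(matched, m, config$cutpoint_rule,
                             config$cv_unit))
    }
  })
  cutpoint_table <- data.table::rbindlist(lapply(class_fits, function(f) {
    data.table::data.table(
      metric = f$metric_name, cutpoint = f$cutpoint, auc = f$auc,
      pct_running_correct = f$pct_running_correct,
      pct_nonrunning_correct = f$pct_nonrunning_correct,
      pct_rest_correct = f$pct_rest_correct,
      pct_other_training_correct = f$pct_other_training_correct)
  }))
  mis_long <- data.table::rbindlist(lapply(class_fits, function(f) {
    if (nrow(f$misclassification) == 0L) return(NULL)
    cbind(metric = f$metric_name, f$misclassification)
  }))
  cv_table <- data.table::rbindlist(lapply(cv_fits, function(cv) {
    s <- cv$summary
    data.table::data.table(metric = cv$metric_name,
                           pooled_accuracy = s$pooled_accuracy,
                           mean_auc = s$mean_auc, min_auc = s$min_auc,
                           full_auc = s$full_auc)
  }))

  cutpoints <- vapply(class_fits[config$validity_classifiers], `[[`, 0,
                      "cutpoint")
  names(cutpoints) <- config$validity_classifiers
  validity <- stage("validate", verbose, validity_matrix(
    matched, cutpoints, config$predictors, config$criteria))

  report <- structure(list(
    cohort_summary = list(
      n_participants = cohort$config$n_participants,
      n_days_generated = length(cohort$day_specs),
      n_days_valid = nrow(metrics),
      retention = filt$retention,
      days_per_category = as.list(table(matched$category)),
      mean_wear_h = mean(metrics$wear_h)),
    cutpoint_table = cutpoint_table,
    misclassification_table = mis_long,
    cv_table = cv_table,
    validity_matrix = validity,
    matched = matched,
    class_fits = class_fits,
    cv_fits = cv_fits,
    provenance = list(config_hash = config_hash(config),
                      seed = config$seed,
                      cutpoint_rule = config$cutpoint_rule,
                      cv_unit = config$cv_unit,
                      package_version = as.character(
                        utils::packageVersion("wristload")))),
    class = "study_report")

  if (!is.null(config$output_dir)) {
    stage("persist", verbose,
          persist_study(report, cohort, metrics, labels, config))
  }
  report
}

persist_study <- function(report, cohort, metrics, labels, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$output_dir, f)
  write_metrics_csv(metrics, p("metrics.csv"))
  write_labels_csv(labels, p("labels.csv"))
  write_labels_csv(cohort$labels, p("ground_truth.csv"))
  write_training_log(cohort$log, p("log.csv"))
  preds <- data.table::copy(report$matched[, .(participant_id, date, category)])
  for (m in names(report$class_fits)) {
    preds[[paste0("pred_", m)]] <- as.integer(report$class_fits[[m]]$predicted)
  }
  preds$date <- format(preds$date)
  data.table::fwrite(preds, p("predictions.csv"))
  data.table::fwrite(report$validity_matrix, p("validity.csv"))
  if (isTRUE(config$persist_epochs)) {
    write_epoch_csv(cohort$epochs, p("epochs.csv"))
  }
  jsonlite::write_json(report_json(report), p("report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(utils::capture.output(print(report)), p("report.txt"))
  invisible(NULL)
}

report_json <- function(report) {
  list(cohort_summary = report$cohort_summary,
       cutpoint_table = report$cutpoint_table,
       misclassification_table = report$misclassification_table,
       cv_table = report$cv_table,
       validity_matrix = report$validity_matrix,
       provenance = report$provenance)
}

#' @export
print.study_report <- function(x, ...) {
  cs <- x$cohort_summary
  cat("== Study report ==\n")
  cat(sprintf("Cohort: %d participants, %d/%d valid days (retention %.1f%%), mean wear %.1f h\n",
              cs$n_participants, cs$n_days_valid, cs$n_days_generated,
              100 * cs$retention, cs$mean_wear_h))
  cat("Days per category:",
      paste(sprintf("%s=%d", names(cs$days_per_category),
                    unlist(cs$days_per_category)), collapse = ", "), "\n")
  cat("\n-- Optimal cutpoints --\n")
  print(x$cutpoint_table)
  cat("\n-- Other-training misclassified as running (%) --\n")
  print(x$misclassification_table)
  cat("\n-- Leave-one-participant-out cross-validation --\n")
  print(x$cv_table)
  cat("\n-- Validity matrix (variance explained) --\n")
  print(x$validity_matrix)
  cat(sprintf("\nProvenance: seed %d, config %s, wristload %s\n",
              x$provenance$seed, x$provenance$config_hash,
              x$provenance$package_version))
  invisible(x)
}
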