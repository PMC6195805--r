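test_that("ROC AUC matches hand-computed cases", {
  expect_equal(roc_curve(c(10, 12, 1, 2), c(T, T, F, F))$auc, 1)
  expect_equal(roc_curve(rep(7, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  # 3 concordant pairs of 4: {5,3} vs {4,1}
  expect_equal(roc_curve(c(5, 3, 4, 1), c(T, T, F, F))$auc, 0.75)
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC equals brute-force pairwise concordance, ties credited 1/2", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    values <- sample(0:20, n, replace = TRUE)  # heavy ties on purpose
    labels <- runif(n) < 0.5
    if (length(unique(labels)) < 2) next
    expect_identical(roc_curve(values, labels)$auc, ref_auc(values, labels))
  }
})

test_that("ROC sensitivity is non-increasing in the threshold", {
  set.seed(42)
  r <- roc_curve(rnorm(100), runif(100) < 0.4)
  expect_true(all(diff(r$sensitivity) <= 0))
  expect_gte(r$auc, 0); expect_lte(r$auc, 1)
})

test_that("optimal cutpoint lands between the classes with stated tie-breaks", {
  r <- roc_curve(c(10, 12, 1, 2), c(T, T, F, F))
  sel <- optimal_cutpoint(r)
  expect_equal(sel$cutpoint, 6)          # midpoint of 2 and 10
  expect_equal(sel$sensitivity, 1)
  expect_equal(sel$specificity, 1)

  # uninformative data: J = 0 everywhere, warn
  r0 <- roc_curve(c(1, 2, 1, 2), c(T, T, F, F))
  expect_warning(sel0 <- optimal_cutpoint(r0), "J <= 0")
  expect_true(sel0$uninformative)

  # enumeration example: max J at threshold 5 (sens 2/3, spec 1)
  r1 <- roc_curve(c(3, 5, 7, 2, 4), c(T, T, T, F, F))
  sel1 <- optimal_cutpoint(r1)
  want <- ref_best_threshold(c(3, 5, 7, 2, 4), c(T, T, T, F, F))
  expect_equal(sel1$threshold, want$threshold)
  expect_equal(sel1$youden_j, want$j)
  expect_equal(sel1$cutpoint, 4.5)       # midpoint of 4 and 5
})

test_that("cutpoint selection equals exhaustive threshold search", {
  set.seed(43)
  for (i in 1:25) {
    n <- sample(10:120, 1)
    values <- round(rnorm(n, 50, 20))
    labels <- values + rnorm(n, 0, 25) > 50
    if (length(unique(labels)) < 2) next
    sel <- suppressWarnings(optimal_cutpoint(roc_curve(values, labels)))
    want <- ref_best_threshold(values, labels)
    expect_equal(sel$youden_j, want$max_j)
    expect_equal(sel$threshold, want$threshold)
    expect_equal(sel$sensitivity, want$sens)
    expect_equal(sel$specificity, want$spec)
  }
})

test_that("classification is inclusive at the cutpoint", {
  expect_true(classify_days(5, 5))
  expect_identical(classify_days(c(1, 2, 3), 10), c(FALSE, FALSE, FALSE))
  set.seed(44)
  v <- rnorm(200); y <- runif(200) < 0.5
  pred <- classify_days(v, 0)
  br <- accuracy_breakdown(pred, data.frame(
    category = ifelse(y, "running", "rest")))
  # confusion-matrix accuracy equals the mean of correctness indicators
  expect_equal(br$accuracy, mean(pred == y))
  expect_equal(br$tp + br$fn + br$fp + br$tn, 200)
})

test_that("accuracy breakdown reports per-activity misclassification", {
  lab <- data.frame(
    category = c(rep("running", 10), rep("rest", 10), rep("other_training", 47)),
    other_activities = c(rep("", 20), rep("cycling", 47)))
  pred <- c(rep(TRUE, 10), rep(FALSE, 10), rep(TRUE, 15), rep(FALSE, 32))
  br <- accuracy_breakdown(pred, lab)
  expect_equal(br$pct_running_correct, 100)
  expect_equal(br$pct_rest_correct, 100)
  mis <- br$misclassification
  expect_identical(mis$activity, "cycling")
  expect_identical(mis$n_occurrences, 47L)
  expect_equal(mis$pct_misclassified, 100 * 15 / 47, tolerance = 1e-12)
  # internal consistency with confusion counts
  expect_equal(br$pct_nonrunning_correct, 100 * br$tn / (br$tn + br$fp))

  # all-correct case: 100% everywhere, 0% misclassification
  all_good <- accuracy_breakdown(c(rep(TRUE, 10), rep(FALSE, 57)),
                                 lab[c(1:10, 11:67), ])
  expect_equal(all_good$pct_nonrunning_correct, 100)
  expect_equal(all_good$misclassification$pct_misclassified, 0)
  # zero-occurrence activities are omitted, not 0/0
  expect_false("swim" %in% all_good$misclassification$activity)
})

test_that("participant-level LOOCV behaves on separable and permuted data", {
  # identical separable data per participant: every fold is perfect
  sep <- data.frame(
    participant_id = rep(c("A", "B", "C"), each = 6),
    m = rep(c(100, 110, 120, 1, 2, 3), 3),
    category = rep(c("running", "running", "running", "rest", "rest", "rest"), 3))
  cv <- loocv_classification(sep, "m")
  expect_true(all(cv$folds$auc == 1))
  expect_equal(cv$summary$pooled_accuracy, 1)

  # permuted labels: mean held-out AUC compatible with 0.5
  set.seed(45)
  n_p <- 20; n_d <- 30
  perm <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:n_p), each = n_d),
    m = rnorm(n_p * n_d),
    category = sample(rep(c("running", "rest"), n_p * n_d / 2)))
  cvp <- suppressWarnings(loocv_classification(perm, "m"))
  aucs <- cvp$folds$auc[cvp$folds$both_classes]
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 1e-9)

  expect_error(loocv_classification(sep[1:12, ], "m"), ">= 3 folds")
})

test_that("AUROC sample size reproduces the published power computation", {
  n <- auroc_sample_size(0.6)
  expect_identical(n$n_per_group, 129L)
  expect_identical(n$n_total, 258L)

  # monotone decreasing in effect size; diverges near the null
  expect_gt(auroc_sample_size(0.55)$n_total, auroc_sample_size(0.6)$n_total)
  expect_gt(auroc_sample_size(0.6)$n_total, auroc_sample_size(0.7)$n_total)
  expect_gt(auroc_sample_size(0.501)$n_total, 10000)

  # independent recomputation of the same closed form at 0.7
  v <- function(th) th / (2 - th) + 2 * th^2 / (1 + th) - 2 * th^2
  n_ref <- ceiling((qnorm(0.975) * sqrt(v(0.5)) + qnorm(0.8) * sqrt(v(0.7)))^2 /
                     (0.7 - 0.5)^2)
  expect_identical(auroc_sample_size(0.7)$n_per_group, as.integer(n_ref))

  expect_error(auroc_sample_size(0.5), "auc_null < auc_alt")
  expect_error(auroc_sample_size(1.2), "auc_alt < 1")
  expect_error(auroc_sample_size(0.6, alpha = 0), "alpha")
})
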