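# Independent reference implementations ("oracles") used to check the
# package's optimised paths. Deliberately naive: per-sample loops, full
# enumeration, two nested loops. They must never share code with R/.

# per-sample ENMO -> epoch means, plain loop
ref_enmo_epochs <- function(raw, calibration = NULL, epoch_s = 5) {
  off <- if (is.null(calibration)) c(0, 0, 0) else calibration$offset
  sc <- if (is.null(calibration)) c(1, 1, 1) else calibration$scale
  n <- nrow(raw)
  enmo <- numeric(n)
  for (i in seq_len(n)) {
    v <- c(off[1] + sc[1] * raw$x[i],
           off[2] + sc[2] * raw$y[i],
           off[3] + sc[3] * raw$z[i])
    enmo[i] <- max(0, sqrt(sum(v^2)) - 1000)
  }
  ids <- floor(raw$time / epoch_s + 1e-9)
  dt <- stats::median(diff(raw$time))
  expected <- round(epoch_s / dt)
  out <- c()
  for (id in sort(unique(ids))) {
    sel <- ids == id
    if (sum(sel) >= expected) out <- c(out, mean(enmo[sel]))
  }
  out
}

# brute-force scan over every contiguous window
ref_most_active <- function(values, wear, w) {
  n <- length(values)
  if (n < w) return(NA_real_)
  best <- NA_real_
  for (i in seq_len(n - w + 1)) {
    idx <- i:(i + w - 1)
    if (all(wear[idx])) {
      m <- mean(values[idx])
      if (is.na(best) || m > best) best <- m
    }
  }
  best
}

# pairwise concordance with ties credited 1/2
ref_auc <- function(values, labels) {
  pos <- values[labels]; neg <- values[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# exhaustive threshold enumeration for Youden's J with the package's stated
# tie-breaks, recomputed from first principles
ref_best_threshold <- function(values, labels) {
  cand <- sort(unique(values))
  sens <- sapply(cand, function(t) mean(values[labels] >= t))
  spec <- sapply(cand, function(t) mean(values[!labels] < t))
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1) {
    bal <- abs(sens[best] - spec[best])
    best <- best[bal == min(bal)]
  }
  best <- best[1]
  list(threshold = cand[best], j = j[best], sens = sens[best],
       spec = spec[best], max_j = max(j))
}

# naive two-loop leave-one-group-out predicted R^2
ref_loocv_r2 <- function(data, predictor, criterion, group = "participant_id") {
  x <- data[[predictor]]; y <- data[[criterion]]
  g <- as.character(data[[group]])
  pred <- rep(NA_real_, length(y))
  for (f in unique(g)) {
    hold <- which(g == f)
    train <- which(g != f)
    fit <- stats::lm(y[train] ~ x[train])
    a <- coef(fit)[1]; b <- coef(fit)[2]
    for (i in hold) pred[i] <- a + b * x[i]
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

# minimal epoch_series builder for metric tests
make_series <- function(values, wear = NULL, epoch_s = 5) {
  epoch_series("T01", as.Date("2016-01-04"), values, wear, epoch_s = epoch_s)
}

# a hand-built day specification in the generator's format
make_spec <- function(sessions = NULL, nonwear = NULL,
                      participant_id = "T01", date = as.Date("2016-01-04")) {
  if (is.null(sessions)) {
    sessions <- data.frame(activity = character(0), start_min = numeric(0),
                           duration_min = numeric(0))
  }
  if (is.null(nonwear)) {
    nonwear <- data.frame(start_min = numeric(0), duration_min = numeric(0))
  }
  list(participant_id = participant_id, date = date,
       category = "manual", sessions = sessions, nonwear = nonwear)
}

# profiles with zero variance everywhere, for exact-count tests
constant_profiles <- function(sedentary_mean = 30) {
  p <- default_profiles()
  for (nm in names(p)) p[[nm]]$epoch_sd <- 0
  p$sedentary$epoch_mean <- sedentary_mean
  p
}

small_cohort_config <- function(...) {
  cohort_config(n_participants = 6, days_per_participant = 10, ...)
}

# the default synthetic cohort's full study, run once and shared between
# test files (it is the most expensive fixture in the suite)
default_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_study(study_config(seed = 7))
    cache
  }
})
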