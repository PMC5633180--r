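#' Derive ground-truth exit events from annotation intervals
#'
#' A bed-exit event occurs at each `Lying -> Sitting-on-bed` or
#' `Lying -> Ambulating` boundary between consecutive annotated intervals; a
#' chair-exit event at each `Sitting-on-chair -> (anything else)` boundary.
#' Each event carries the activity window spanned by the two intervals of
#' the transition, used by the matching criteria.
#'
#' @param truth Data frame of annotation intervals (`start`, `end`, `label`),
#'   time-ordered and non-overlapping.
#'
#' @return Data frame of events: `time` (start of the post-transition
#'   interval), `type`, `win_start`, `win_end`.
#' @export
derive_exit_events <- function(truth) {
  empty <- data.frame(time = numeric(0), type = character(0),
                      win_start = numeric(0), win_end = numeric(0),
                      stringsAsFactors = FALSE)
  n <- nrow(truth)
  if (n < 2) return(empty)
  out <- empty
  for (k in 2:n) {
    prev <- truth$label[k - 1]
    cur <- truth$label[k]
    type <- NULL
    if (prev == "Lying" && cur %in% c("Sitting-on-bed", "Ambulating")) {
      type <- "bed-exit"
    } else if (prev == "Sitting-on-chair" && cur != "Sitting-on-chair") {
      type <- "chair-exit"
    }
    if (!is.null(type)) {
      out <- rbind(out, data.frame(
        time = truth$start[k], type = type,
        win_start = truth$start[k - 1], win_end = truth$end[k],
        stringsAsFactors = FALSE
      ))
    }
  }
  out
}

#' Match alarms against ground-truth exit events
#'
#' An alarm is a true positive for an event if it fires inside the event's
#' activity window (the person is actually performing an activity of
#' interest) or at most `tol` seconds before the event's start (the real
#' activity follows the alert within the tolerance). Each event consumes at
#' most one alarm -- the earliest qualifying one; remaining alarms are false
#' positives and unmatched events are false negatives.
#'
#' @param alarms Data frame from [detect_exits()] (`time`, `type`).
#' @param events Data frame from [derive_exit_events()].
#' @param tol Anticipation tolerance in seconds (default 5).
#'
#' @return List with counts `TP`, `FP`, `FN`, the matched `pairs` data frame
#'   (`event_time`, `alarm_time`, `delay`) and the vector of `delays`
#'   (alarm time minus event time).
#' @export
match_alarms <- function(alarms, events, tol = 5) {
  a_time <- sort(alarms$time)
  used <- rep(FALSE, length(a_time))
  pairs <- data.frame(event_time = numeric(0), alarm_time = numeric(0),
                      delay = numeric(0))
  ev <- events[order(events$time), , drop = FALSE]
  for (k in seq_len(nrow(ev))) {
    ok <- !used &
      ((a_time >= ev$win_start[k] & a_time <= ev$win_end[k]) |
         (a_time <= ev$time[k] & ev$time[k] - a_time <= tol))
    hit <- which(ok)
    if (length(hit) > 0) {
      j <- hit[1]  # earliest qualifying alarm
      used[j] <- TRUE
      pairs <- rbind(pairs, data.frame(
        event_time = ev$time[k], alarm_time = a_time[j],
        delay = a_time[j] - ev$time[k]
      ))
    }
  }
  TP <- sum(used)
  list(TP = TP, FP = length(a_time) - TP, FN = nrow(ev) - TP,
       pairs = pairs, delays = pairs$delay)
}

#' Recall, precision and F-score from event counts
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`, F-score their
#' harmonic mean; `0/0` is 0 by convention.
#'
#' @param TP,FP,FN Non-negative counts (vectorized).
#' @return Data frame with columns `recall`, `precision`, `fscore`.
#' @export
metrics <- function(TP, FP, FN) {
  stopifnot(all(TP >= 0), all(FP >= 0), all(FN >= 0))
  recall <- ifelse(TP + FN > 0, TP / (TP + FN), 0)
  precision <- ifelse(TP + FP > 0, TP / (TP + FP), 0)
  fscore <- ifelse(recall + precision > 0,
                   2 * precision * recall / (precision + recall), 0)
  data.frame(recall = recall, precision = precision, fscore = fscore)
}

#' Macro aggregation of per-patient metrics
#'
#' Mean and sample standard deviation of each per-patient metric across the
#' cohort, in percent. This is the macro average (per-patient mean), not a
#' pooling of counts across patients.
#'
#' @param per_patient Data frame with columns `recall`, `precision`,
#'   `fscore` (fractions), one row per patient.
#' @return Data frame with one row per metric: `metric`, `mean_pct`,
#'   `sd_pct`.
#' @export
aggregate_cohort <- function(per_patient) {
  stopifnot(nrow(per_patient) >= 1)
  mets <- c("recall", "precision", "fscore")
  data.frame(
    metric = mets,
    mean_pct = vapply(mets, function(m) 100 * mean(per_patient[[m]]), 0),
    sd_pct = vapply(mets, function(m) {
      if (nrow(per_patient) < 2) 0 else 100 * stats::sd(per_patient[[m]])
    }, 0),
    row.names = NULL
  )
}

#' Patient-level leave-one-out cross-validation
#'
#' For each patient `i`: patient `i` is the test set, the next patient in a
#' fixed rotation is the validation set used for model parameter selection
#' ([select_model()]), and all remaining patients form the training set.
#' Every patient is tested exactly once and is never seen by the model that
#' scores it.
#'
#' @param cohort List of at least 3 [patient_record()] objects.
#' @param C_grid,T_grid Parameter grids passed to [select_model()].
#' @param cfg A [pipeline_config()].
#' @param seed Integer seed (weight search and subsampling).
#'
#' @return List with `per_patient` (data frame: patient, events, TP, FP, FN,
#'   recall, precision, fscore, selected C and T), `summary` (the
#'   [aggregate_cohort()] table), `delays` (pooled alarm delays of matched
#'   events, seconds) and `median_delay`.
#' @export
loocv <- function(cohort, C_grid = c(0.1, 1, 10, 100), T_grid = c(4.8),
                  cfg = pipeline_config(), seed = 1) {
  n <- length(cohort)
  if (n < 3) stop("leave-one-out protocol needs at least 3 patients")
  rows <- vector("list", n)
  delays <- numeric(0)
  for (i in seq_len(n)) {
    val_i <- if (i == n) 1L else i + 1L
    train_ix <- setdiff(seq_len(n), c(i, val_i))
    sel <- select_model(cohort[train_ix], cohort[[val_i]],
                        C_grid, T_grid, cfg, seed = seed + i)
    test <- cohort[[i]]
    fm <- extract_features(test, cfg$feature)
    P <- predict_proba(sel$model, feature_matrix(fm, cfg$feature))
    acfg <- alarm_config(T = sel$T_star, refractory = cfg$refractory)
    alarms <- detect_exits(score_windows(probs_frame(fm$t, P), acfg), acfg)
    events <- derive_exit_events(test$truth)
    m <- match_alarms(alarms, events, tol = cfg$match_tol)
    met <- metrics(m$TP, m$FP, m$FN)
    rows[[i]] <- data.frame(
      patient = test$patient_id, events = nrow(events),
      TP = m$TP, FP = m$FP, FN = m$FN,
      recall = met$recall, precision = met$precision, fscore = met$fscore,
      C = sel$C_star, T = sel$T_star, stringsAsFactors = FALSE
    )
    delays <- c(delays, m$delays)
  }
  per_patient <- do.call(rbind, rows)
  list(per_patient = per_patient,
       summary = aggregate_cohort(per_patient),
       delays = delays,
       median_delay = if (length(delays) > 0) stats::median(delays) else NA_real_)
}

#' Independent t-test between per-patient metrics of two methods
#'
#' Two-sample pooled-variance t-test of the null hypothesis that the two
#' methods perform the same, applied to per-patient metric values.
#'
#' @param metric_a,metric_b Numeric vectors of per-patient metric values
#'   (each length >= 2).
#' @return List with `t` (statistic) and `p` (two-sided p-value). When both
#'   samples have zero variance and equal means, `t = 0` and `p = 1`.
#' @export
compare_methods <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) >= 2, length(metric_b) >= 2)
  if (stats::sd(metric_a) == 0 && stats::sd(metric_b) == 0) {
    if (mean(metric_a) == mean(metric_b)) return(list(t = 0, p = 1))
    return(list(t = Inf * sign(mean(metric_a) - mean(metric_b)), p = 0))
  }
  tt <- stats::t.test(metric_a, metric_b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Per-patient exit-detection counts from the hospital pilot deployment
#'
#' Published per-patient true-positive, false-positive and false-negative
#' bed/chair-exit counts for the 23 evaluable patients of the hospital pilot
#' of this monitoring system: the fixed-time-window score-function method
#' (4.8 s windows) and the earlier conditional-random-field comparison
#' method evaluated on the same patients. These counts are inputs for
#' validating the metric and aggregation definitions.
#'
#' @return Data frame with columns `patient`, `events`, `TP_fixed`,
#'   `FP_fixed`, `FN_fixed`, `TP_crf`, `FP_crf`, `FN_crf`.
#' @export
pilot_trial_counts <- function() {
  counts <- matrix(c(
    5, 2, 3, 3, 2, 28, 3,
    6, 4, 3, 2, 5, 5, 1,
    5, 4, 2, 1, 5, 1, 0,
    4, 4, 0, 0, 4, 13, 0,
    6, 6, 4, 0, 5, 3, 1,
    4, 3, 3, 1, 3, 4, 1,
    2, 2, 0, 0, 2, 3, 0,
    3, 3, 1, 0, 3, 3, 0,
    6, 5, 2, 1, 3, 3, 3,
    6, 3, 5, 3, 2, 12, 4,
    3, 2, 0, 1, 2, 0, 1,
    5, 3, 6, 2, 5, 7, 0,
    6, 6, 6, 0, 6, 46, 0,
    5, 4, 2, 1, 4, 4, 1,
    6, 6, 1, 0, 6, 22, 0,
    7, 5, 3, 2, 6, 4, 1,
    3, 2, 2, 1, 2, 1, 1,
    4, 4, 0, 0, 4, 4, 0,
    6, 4, 3, 2, 5, 16, 1,
    6, 4, 3, 2, 6, 33, 0,
    6, 6, 3, 0, 6, 9, 0,
    6, 6, 3, 0, 6, 4, 0,
    5, 5, 1, 0, 5, 19, 0
  ), ncol = 7, byrow = TRUE)
  data.frame(
    patient = paste0("p.", 1:23),
    events = counts[, 1],
    TP_fixed = counts[, 2], FP_fixed = counts[, 3], FN_fixed = counts[, 4],
    TP_crf = counts[, 5], FP_crf = counts[, 6], FN_crf = counts[, 7],
    stringsAsFactors = FALSE
  )
}
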