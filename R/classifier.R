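#' Train a class-weighted multiclass SVM
#'
#' Soft-margin SVM in the one-against-one multiclass scheme (6 pairwise
#' machines for the 4 activity classes), where each training sample's slack
#' penalty is `C * s_k` for its class `k`: raising a minority class's weight
#' makes its misclassifications costlier, countering the heavy class
#' imbalance of ward activity data. Features are standardized to the
#' training split (zero mean, unit variance); the scaling is stored in the
#' model and applied at prediction time. Calibrated class probabilities are
#' obtained by pairwise-coupled Platt scaling.
#'
#' @param X Numeric feature matrix (rows = readings).
#' @param y Class labels (character or factor), at least two classes.
#' @param C Regularization constant (> 0).
#' @param weights Named positive per-class weights `s_k`; default 1 for every
#'   class (plain SVM).
#' @param kernel `"radial"` (default; RBF with `gamma = 1 / ncol(X)` unless
#'   given) or `"linear"`.
#' @param gamma RBF kernel width; default `1 / ncol(X)`.
#' @param probability Fit the Platt probability model (default `TRUE`).
#'
#' @return Object of class `wsvm_model`.
#' @export
train_wsvm <- function(X, y, C = 1, weights = NULL,
                       kernel = c("radial", "linear"), gamma = NULL,
                       probability = TRUE) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  bad <- which(!apply(X, 1, function(r) all(is.finite(r))))
  if (length(bad) > 0) {
    stop("non-finite feature values in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  y <- as.character(y)
  lev <- if (all(y %in% activity_levels())) {
    intersect(activity_levels(), unique(y))
  } else {
    sort(unique(y))
  }
  if (length(lev) < 2) stop("training data contains a single class")
  yf <- factor(y, levels = lev)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(lev)), lev)
  if (is.null(names(weights)) || !all(lev %in% names(weights))) {
    stop("weights must be named with one entry per class")
  }
  if (any(weights <= 0)) stop("class weights must be positive")
  if (is.null(gamma)) gamma <- 1 / ncol(X)

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- scale(X, center = ctr, scale = scl)

  fit <- e1071::svm(x = Xs, y = yf, cost = C,
                    class.weights = weights[lev],
                    kernel = kernel, gamma = gamma,
                    probability = probability, scale = FALSE)
  structure(list(svm = fit, center = ctr, scale = scl, levels = lev,
                 C = C, weights = weights[lev], kernel = kernel,
                 gamma = gamma, probability = probability),
            class = "wsvm_model")
}

#' @export
print.wsvm_model <- function(x, ...) {
  cat(sprintf("<wsvm_model> %d classes, %s kernel, C = %g, weights: %s\n",
              length(x$levels), x$kernel, x$C,
              paste(sprintf("%s=%.3g", x$levels, x$weights), collapse = " ")))
  invisible(x)
}

scale_features <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$center)) {
    stop("feature dimension mismatch: model expects ", length(model$center),
         " columns, got ", ncol(X))
  }
  scale(X, center = model$center, scale = model$scale)
}

#' Calibrated class probabilities for new readings
#'
#' @param model A [train_wsvm()] model fitted with `probability = TRUE`.
#' @param X Numeric feature matrix on the raw (unscaled) feature scale.
#'
#' @return Matrix with one row per reading and one column per class (in the
#'   model's level order); rows are distributions summing to 1.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "wsvm_model"))
  if (!model$probability) stop("model was trained without a probability model")
  Xs <- scale_features(model, X)
  pred <- stats::predict(model$svm, Xs, probability = TRUE)
  P <- attr(pred, "probabilities")
  P <- P[, model$levels, drop = FALSE]
  P / rowSums(P)
}

#' Predicted activity labels (pairwise-vote decision)
#'
#' @param model A [train_wsvm()] model.
#' @param X Numeric feature matrix on the raw feature scale.
#' @return Character vector of predicted labels.
#' @export
predict_activity <- function(model, X) {
  Xs <- scale_features(model, X)
  as.character(stats::predict(model$svm, Xs))
}

#' Pairwise decision values
#'
#' One-against-one decision values of each binary machine, mainly for
#' cross-checking the trainer against reference solvers.
#'
#' @param model A [train_wsvm()] model.
#' @param X Numeric feature matrix on the raw feature scale.
#' @return Matrix of decision values (one column per class pair).
#' @export
decision_values <- function(model, X) {
  Xs <- scale_features(model, X)
  attr(stats::predict(model$svm, Xs, decision.values = TRUE),
       "decision.values")
}

#' Macro-averaged F-score of a classification
#'
#' Per-class F-score (one-vs-rest) averaged over classes; classes absent
#' from both truth and prediction contribute 0 only if listed in `levels`.
#'
#' @param truth,pred Label vectors of equal length.
#' @param levels Classes to average over; default the classes present in
#'   `truth`.
#' @return Scalar in `[0, 1]`.
#' @export
macro_f_score <- function(truth, pred, levels = NULL) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (is.null(levels)) levels <- unique(truth)
  f <- vapply(levels, function(k) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f)
}

#' Search class weights by CMA-ES
#'
#' The per-class slack weights `s_k` are unknown at training time, so they
#' are found by a second optimization: maximize the macro-averaged
#' classification F-score of the weighted SVM on the training split. The
#' search runs in `log10`-weight space (weights clipped to `[1e-2, 1e2]`)
#' with CMA-ES restarts from random initial weight sets; deterministic given
#' `seed`.
#'
#' @param X,y Training features and labels.
#' @param C Regularization constant passed to each candidate model.
#' @param objective Optional custom objective `function(weights) -> scalar`
#'   to maximize (weights on the linear scale); default is the macro F-score
#'   of the candidate model on `(X, y)`.
#' @param budget CMA-ES evaluations per restart (default 2000).
#' @param n_restarts Number of random initial weight sets (default 20; the
#'   full-scale protocol used 200).
#' @param seed Integer seed.
#' @param kernel,gamma Kernel specification, as in [train_wsvm()].
#'
#' @return List of class `weight_search` with elements `weights` (named,
#'   linear scale), `objective` (best objective found), `evals`, `seed` and
#'   `incumbent` (best objective after each generation, non-decreasing).
#' @export
optimize_class_weights <- function(X, y, C = 1, objective = NULL,
                                   budget = 2000, n_restarts = 20, seed = 1,
                                   kernel = "radial", gamma = NULL) {
  stopifnot(budget >= 1, n_restarts >= 1)
  X <- as.matrix(X)
  y <- as.character(y)
  lev <- if (all(y %in% activity_levels())) {
    intersect(activity_levels(), unique(y))
  } else {
    sort(unique(y))
  }
  k <- length(lev)
  if (is.null(objective)) {
    objective <- function(w) {
      m <- train_wsvm(X, y, C = C, weights = stats::setNames(w, lev),
                      kernel = kernel, gamma = gamma, probability = FALSE)
      macro_f_score(y, predict_activity(m, X), levels = lev)
    }
  }
  neg_log_obj <- function(lw) -objective(stats::setNames(10^lw, lev))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  restart_seeds <- sample.int(2^31 - 1, n_restarts)

  best <- NULL
  evals <- 0L
  incumbent <- numeric(0)
  for (r in seq_len(n_restarts)) {
    set.seed(restart_seeds[r])
    x0 <- stats::runif(k, -1, 1)
    res <- tryCatch(
      cma_es(neg_log_obj, x0, sigma0 = 0.5, budget = budget,
             lower = -2, upper = 2, seed = restart_seeds[r]),
      error = function(e) {
        warning("weight-search restart ", r, " failed: ", conditionMessage(e))
        NULL
      }
    )
    if (is.null(res)) next
    evals <- evals + res$evals
    inc_r <- -res$incumbent
    if (length(inc_r) == 0) inc_r <- -res$value
    prev_best <- if (length(incumbent) > 0) max(incumbent) else -Inf
    incumbent <- c(incumbent, cummax(pmax(inc_r, prev_best)))
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all weight-search restarts failed")
  structure(list(weights = stats::setNames(10^best$par, lev),
                 objective = -best$value, evals = evals, seed = seed,
                 incumbent = incumbent),
            class = "weight_search")
}

#' Pipeline tuning configuration
#'
#' Bundles the knobs shared by [select_model()] and [loocv()]. The weight
#' search and training-set sizes default to desk-scale values so a full
#' leave-one-out run completes in minutes; `weight_budget` and
#' `weight_restarts` can be raised toward the full-scale protocol (2000
#' evaluations, up to 200 restarts).
#'
#' @param feature A [feature_config()].
#' @param refractory Alarm refractory period in seconds (default 1.75).
#' @param match_tol Event-matching tolerance in seconds (default 5).
#' @param weight_budget CMA-ES evaluations per restart in the weight search.
#' @param weight_restarts CMA-ES restarts in the weight search.
#' @param search_max_rows Stratified row cap for the weight-search training
#'   subsample (the search retrains an SVM per candidate, so it runs on a
#'   subsample; the final model trains on up to `fit_max_rows` rows).
#' @param fit_max_rows Stratified row cap for fitting the final model.
#'
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(feature = feature_config(), refractory = 1.75,
                            match_tol = 5, weight_budget = 40,
                            weight_restarts = 1, search_max_rows = 1200,
                            fit_max_rows = 4000) {
  structure(list(feature = feature, refractory = refractory,
                 match_tol = match_tol, weight_budget = weight_budget,
                 weight_restarts = weight_restarts,
                 search_max_rows = search_max_rows,
                 fit_max_rows = fit_max_rows),
            class = "pipeline_config")
}

# stratified row subsample keeping every class represented
stratified_cap <- function(y, cap, seed) {
  n <- length(y)
  if (n <= cap) return(seq_len(n))
  set.seed(seed)
  idx <- unlist(lapply(split(seq_len(n), y), function(ix) {
    take <- max(2L, round(cap * length(ix) / n))
    if (length(ix) <= take) ix else sample(ix, take)
  }))
  sort(idx)
}

# labelled training matrix pooled over patient records
pooled_training_data <- function(records, cfg) {
  parts <- lapply(records, function(r) {
    fm <- extract_features(r, cfg$feature)
    lab <- label_readings(r)
    keep <- !is.na(lab)
    list(X = feature_matrix(fm[keep, , drop = FALSE], cfg$feature),
         y = lab[keep])
  })
  list(X = do.call(rbind, lapply(parts, `[[`, "X")),
       y = unlist(lapply(parts, `[[`, "y")))
}

#' Select model parameters on a validation patient
#'
#' For each regularization constant in `C_grid`, runs the CMA-ES class-weight
#' search on the pooled training patients, fits the weighted SVM, and scores
#' bed/chair-exit detection on the held-out validation patient for every
#' score-window length in `T_grid` (window lengths are confined to
#' `[0.1, 5]` s, twice the minimum posture-transition time). Returns the
#' configuration with the highest exit-detection F-score on the validation
#' patient.
#'
#' @param train List of [patient_record()] used for training.
#' @param val A single [patient_record()] for validation (disjoint from
#'   `train`).
#' @param C_grid Numeric vector of candidate regularization constants.
#' @param T_grid Numeric vector of candidate score-window lengths (seconds).
#' @param cfg A [pipeline_config()].
#' @param seed Integer seed for the weight search and subsampling.
#'
#' @return List with `model` (the selected [train_wsvm()] fit), `T_star`,
#'   `C_star`, `weights`, `val_fscore` and the full `grid` of validation
#'   scores.
#' @export
select_model <- function(train, val, C_grid, T_grid,
                         cfg = pipeline_config(), seed = 1) {
  if (length(C_grid) == 0 || length(T_grid) == 0) stop("empty parameter grid")
  if (any(T_grid < 0.1 | T_grid > 5)) {
    stop("score-window lengths must lie in [0.1, 5] s")
  }
  td <- pooled_training_data(train, cfg)
  idx_fit <- stratified_cap(td$y, cfg$fit_max_rows, seed)
  idx_search <- stratified_cap(td$y, cfg$search_max_rows, seed + 1L)

  val_fm <- extract_features(val, cfg$feature)
  val_X <- feature_matrix(val_fm, cfg$feature)
  val_events <- derive_exit_events(val$truth)

  grid <- expand.grid(C = C_grid, T = T_grid)
  grid$fscore <- NA_real_
  best <- NULL
  for (C in C_grid) {
    ws <- optimize_class_weights(td$X[idx_search, , drop = FALSE],
                                 td$y[idx_search], C = C,
                                 budget = cfg$weight_budget,
                                 n_restarts = cfg$weight_restarts,
                                 seed = seed)
    model <- train_wsvm(td$X[idx_fit, , drop = FALSE], td$y[idx_fit],
                        C = C, weights = ws$weights, probability = TRUE)
    P <- predict_proba(model, val_X)
    probs <- probs_frame(val_fm$t, P)
    for (T in T_grid) {
      acfg <- alarm_config(T = T, refractory = cfg$refractory)
      alarms <- detect_exits(score_windows(probs, acfg), acfg)
      m <- match_alarms(alarms, val_events, tol = cfg$match_tol)
      f <- metrics(m$TP, m$FP, m$FN)$fscore
      grid$fscore[grid$C == C & grid$T == T] <- f
      if (is.null(best) || f > best$val_fscore) {
        best <- list(model = model, T_star = T, C_star = C,
                     weights = ws$weights, val_fscore = f)
      }
    }
  }
  best$grid <- grid
  best
}

#' Timestamped probability frame
#'
#' Joins reading timestamps with a class-probability matrix into the frame
#' consumed by [score_windows()].
#'
#' @param t Reading timestamps (seconds).
#' @param P Probability matrix with class-named columns.
#' @return Data frame with a `t` column followed by one column per class.
#' @export
probs_frame <- function(t, P) {
  stopifnot(length(t) == nrow(P))
  cbind(data.frame(t = t), as.data.frame(P, optional = TRUE))
}
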