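test_that("unit class weights reduce to the standard soft-margin SVM", {
  toy <- toy_two_class()
  m_w <- train_wsvm(toy$X, toy$y, C = 1, weights = c(pos = 1, neg = 1),
                    kernel = "linear", probability = FALSE)
  fit_ref <- e1071::svm(x = scale(toy$X), y = factor(toy$y, m_w$levels),
                        cost = 1, kernel = "linear", scale = FALSE)
  d_w <- as.numeric(decision_values(m_w, toy$X))
  d_ref <- as.numeric(attr(predict(fit_ref, scale(toy$X),
                                   decision.values = TRUE),
                           "decision.values"))
  expect_equal(d_w, d_ref, tolerance = 1e-6)
})

test_that("weighted trainer agrees with an independent dual-QP oracle", {
  skip_if_not_installed("kernlab")
  toy <- toy_two_class(n = 12, gap = 2)
  C <- 1
  m <- train_wsvm(toy$X, toy$y, C = C, weights = c(pos = 1, neg = 1),
                  kernel = "linear", probability = FALSE)
  Xs <- scale(toy$X)
  # libsvm's positive class is the one appearing first in the training data
  yv <- ifelse(toy$y == toy$y[1], 1, -1)
  K <- Xs %*% t(Xs)
  n <- length(yv)
  # solve the soft-margin dual: max sum(a) - 1/2 a' (yy'K) a, 0<=a<=C, y'a=0
  H <- (yv %o% yv) * K + diag(1e-10, n)
  sol <- kernlab::ipop(c = matrix(-1, n), H = H,
                       A = matrix(yv, 1), b = 0, r = 0,
                       l = matrix(0, n), u = matrix(C, n), sigf = 9)
  a <- kernlab::primal(sol)
  w <- colSums(a * yv * Xs)
  on_margin <- which(a > 1e-6 & a < C - 1e-6)
  b <- mean(yv[on_margin] - Xs[on_margin, ] %*% w)
  d_oracle <- as.numeric(Xs %*% w + b)

  d_pkg <- as.numeric(decision_values(m, toy$X))
  expect_equal(d_pkg, d_oracle, tolerance = 2e-3)
})

test_that("a separable one-point-per-class set trains to zero error", {
  X <- rbind(c(0, 0), c(0, 4), c(4, 0), c(4, 4))
  y <- activity_levels()
  m <- train_wsvm(X, y, C = 100, kernel = "linear", probability = FALSE)
  expect_equal(predict_activity(m, X), y)
})

test_that("raising the minority weight raises minority recall", {
  set.seed(8)
  n_maj <- 190; n_min <- 10
  X <- rbind(matrix(rnorm(2 * n_maj, 0, 1.4), ncol = 2),
             matrix(rnorm(2 * n_min, 1.6, 1.4), ncol = 2))
  y <- c(rep("maj", n_maj), rep("min", n_min))
  rec_of <- function(w_min) {
    m <- train_wsvm(X, y, C = 1, weights = c(maj = 1, min = w_min),
                    probability = FALSE)
    pred <- predict_activity(m, X)
    sum(pred == "min" & y == "min") / n_min
  }
  expect_gt(rec_of(10), rec_of(1))
})

test_that("probability rows are distributions and deterministic", {
  rec <- synthesize_trial(trial_script(1), seed = 3)
  fm <- extract_features(rec)
  X <- feature_matrix(fm)
  y <- label_readings(rec)
  m <- train_wsvm(X, y)
  P <- predict_proba(m, X[1:50, ])
  expect_equal(unname(rowSums(P)), rep(1, 50), tolerance = 1e-9)
  expect_true(all(P >= 0))
  expect_equal(colnames(P), intersect(activity_levels(), unique(y)))
  # duplicated rows give identical probability rows
  P2 <- predict_proba(m, X[c(1, 1), ])
  expect_equal(P2[1, ], P2[2, ])
  # argmax recovers the label on most training points of this easy task
  pred <- colnames(P)[max.col(predict_proba(m, X))]
  expect_gt(mean(pred == y), 0.9)
})

test_that("degenerate training inputs are rejected informatively", {
  X <- matrix(rnorm(20), ncol = 2)
  expect_error(train_wsvm(X, rep("Lying", 10)), "single class")
  X[3, 1] <- NaN
  expect_error(train_wsvm(X, rep(c("a", "b"), 5)), "row")
  m <- train_wsvm(matrix(rnorm(20), ncol = 2), rep(c("a", "b"), 5),
                  probability = FALSE)
  expect_error(predict_activity(m, matrix(0, 2, 5)), "dimension mismatch")
})

test_that("the prediction pipeline is invariant to a train-split shift", {
  toy <- toy_two_class(n = 30, gap = 1)
  shift <- c(5, -3)
  m1 <- train_wsvm(toy$X, toy$y, probability = FALSE)
  m2 <- train_wsvm(sweep(toy$X, 2, shift, "+"), toy$y, probability = FALSE)
  Xnew <- matrix(rnorm(20), ncol = 2)
  expect_equal(predict_activity(m1, Xnew),
               predict_activity(m2, sweep(Xnew, 2, shift, "+")))
})

test_that("CMA-ES minimizes smooth test functions deterministically", {
  sphere <- function(x) sum((x - c(1, -2, 0.5))^2)
  res <- cma_es(sphere, c(0, 0, 0), sigma0 = 0.5, budget = 1500, seed = 4)
  expect_lt(res$value, 1e-8)
  expect_equal(res$par, c(1, -2, 0.5), tolerance = 1e-3)
  res2 <- cma_es(sphere, c(0, 0, 0), sigma0 = 0.5, budget = 1500, seed = 4)
  expect_identical(res$par, res2$par)
  # incumbent is monotone non-increasing and respects box constraints
  expect_true(all(diff(res$incumbent) <= 0))
  resb <- cma_es(sphere, c(0, 0, 0), sigma0 = 0.5, budget = 600,
                 lower = -0.5, upper = 0.5, seed = 4)
  expect_true(all(resb$par >= -0.5 & resb$par <= 0.5))
  expect_equal(resb$value, sphere(c(0.5, -0.5, 0.5)), tolerance = 1e-4)
})

test_that("the class-weight search maximizes macro F deterministically", {
  # constant objective: any point is optimal; the value is the constant
  X <- matrix(rnorm(40), ncol = 2)
  y <- rep(c("a", "b"), 10)
  res <- optimize_class_weights(X, y, objective = function(w) 0.42,
                                budget = 10, n_restarts = 2, seed = 1)
  expect_equal(res$objective, 0.42)
  # balanced separable data reaches perfect macro F
  toy <- toy_two_class(n = 15, gap = 4)
  res <- optimize_class_weights(toy$X, toy$y, C = 10, budget = 15,
                                n_restarts = 1, seed = 2)
  expect_equal(res$objective, 1.0)
  expect_true(all(res$weights >= 1e-2 & res$weights <= 1e2))
  # incumbent objective never decreases; same seed reproduces the result
  expect_true(all(diff(res$incumbent) >= 0))
  res2 <- optimize_class_weights(toy$X, toy$y, C = 10, budget = 15,
                                 n_restarts = 1, seed = 2)
  expect_identical(res$weights, res2$weights)
})

test_that("macro F-score averages per-class F over the label set", {
  truth <- c("a", "a", "b", "b")
  pred <- c("a", "b", "b", "b")
  # class a: P=1, R=1/2, F=2/3; class b: P=2/3, R=1, F=4/5
  expect_equal(macro_f_score(truth, pred), (2 / 3 + 4 / 5) / 2)
  expect_equal(macro_f_score(truth, truth), 1)
})

test_that("model selection returns the argmax of the validation grid", {
  coh <- synthesize_cohort(3, sim_config_low_noise(), seed = 21)
  cfg <- pipeline_config(weight_budget = 6, weight_restarts = 1,
                         search_max_rows = 300, fit_max_rows = 1500)
  sel <- select_model(coh$records[1], coh$records[[2]],
                      C_grid = 1, T_grid = 4.8, cfg, seed = 5)
  expect_equal(sel$C_star, 1)
  expect_equal(sel$T_star, 4.8)
  sel2 <- select_model(coh$records[1], coh$records[[2]],
                       C_grid = 1, T_grid = c(2.4, 4.8), cfg, seed = 5)
  expect_gte(sel2$val_fscore, max(sel2$grid$fscore) - 1e-12)
  expect_error(select_model(coh$records[1], coh$records[[2]],
                            numeric(0), 4.8, cfg), "empty")
  expect_error(select_model(coh$records[1], coh$records[[2]],
                            1, 7, cfg), "0.1, 5")
})
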