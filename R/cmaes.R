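#' Covariance matrix adaptation evolution strategy (CMA-ES)
#'
#' Derivative-free stochastic minimizer used by the class-weight search.
#' Standard (mu/mu_w, lambda) formulation with weighted recombination,
#' cumulative step-size adaptation and rank-one plus rank-mu covariance
#' updates. Box constraints are handled by projecting sampled candidates
#' onto the box before evaluation and recombination.
#'
#' @param fn Objective function of a numeric vector, to be minimized.
#' @param x0 Numeric start vector.
#' @param sigma0 Initial global step size.
#' @param budget Maximum number of function evaluations.
#' @param lower,upper Box bounds (scalars or vectors).
#' @param lambda Population size; default `4 + floor(3 * log(n))`.
#' @param seed Optional integer seed (local RNG state; the caller's RNG is
#'   restored on exit).
#'
#' @return List with `par` (best point found), `value` (its objective),
#'   `evals` (evaluations used) and `incumbent` (best-so-far objective after
#'   each generation, non-increasing).
#' @export
cma_es <- function(fn, x0, sigma0 = 0.5, budget = 1000,
                   lower = -Inf, upper = Inf, lambda = NULL, seed = NULL) {
  n <- length(x0)
  stopifnot(n >= 1, budget >= 1, sigma0 > 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  clip <- function(x) pmin(pmax(x, lower), upper)

  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)

  cs <- (mueff + 2) / (n + mueff + 5)
  ds <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  m <- clip(as.numeric(x0))
  sigma <- sigma0
  C <- diag(n)
  ps <- pc <- numeric(n)
  eig <- eigen(C, symmetric = TRUE)

  best_x <- m
  best_f <- fn(m)
  evals <- 1L
  incumbent <- numeric(0)

  while (evals < budget) {
    k <- min(lambda, budget - evals)
    B <- eig$vectors
    D <- sqrt(pmax(eig$values, .Machine$double.eps))
    Z <- matrix(stats::rnorm(n * k), n, k)
    Y <- B %*% (D * Z)
    X <- clip(m + sigma * Y)
    f <- apply(X, 2, fn)
    evals <- evals + k
    ord <- order(f)
    if (f[ord[1]] < best_f) {
      best_f <- f[ord[1]]
      best_x <- X[, ord[1]]
    }
    incumbent <- c(incumbent, best_f)
    if (k < mu) break  # budget exhausted mid-generation

    sel <- ord[seq_len(mu)]
    Ysel <- (X[, sel, drop = FALSE] - m) / sigma  # post-clip steps
    ybar <- as.numeric(Ysel %*% w)
    m <- m + sigma * ybar

    Cinvsqrt <- B %*% ((1 / D) * t(B))
    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mueff) * as.numeric(Cinvsqrt %*% ybar)
    hsig <- as.numeric(
      sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * evals / lambda)) / chiN <
        1.4 + 2 / (n + 1)
    )
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ybar
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * Ysel %*% (w * t(Ysel))
    C <- (C + t(C)) / 2
    sigma <- sigma * exp((cs / ds) * (sqrt(sum(ps^2)) / chiN - 1))
    if (!is.finite(sigma) || sigma > 1e6) sigma <- 1e6
    eig <- eigen(C, symmetric = TRUE)
    if (any(!is.finite(eig$values))) {  # numerical degeneracy: restart shape
      C <- diag(n)
      eig <- eigen(C, symmetric = TRUE)
      ps <- pc <- numeric(n)
    }
  }
  list(par = best_x, value = best_f, evals = evals, incumbent = incumbent)
}
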