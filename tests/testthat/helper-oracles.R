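# Independent numerical minimizers used as oracles. Both penalized objectives
# are rewritten with positive/negative coefficient parts, which makes them
# smooth box-constrained problems solvable by L-BFGS-B — a route entirely
# independent of the package's coordinate-descent solvers.

brute_enet <- function(x, y, alpha, lambda, n_starts = 3, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  fn <- function(par) {
    beta <- par[1:p] - par[(p + 1):(2 * p)]
    sum((y - x %*% beta)^2) / (2 * n) +
      lambda * (alpha * sum(par) + (1 - alpha) / 2 * sum(beta^2))
  }
  best <- NULL
  set.seed(seed)
  starts <- c(list(rep(0, 2 * p)),
              replicate(n_starts - 1, abs(rnorm(2 * p, sd = 0.3)),
                        simplify = FALSE))
  for (st in starts) {
    o <- optim(st, fn, method = "L-BFGS-B", lower = 0,
               control = list(maxit = 2000, factr = 1e4))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best$par[1:p] - best$par[(p + 1):(2 * p)]
}

brute_lassosum <- function(R, r, lambda, s, n_starts = 3, seed = 1) {
  p <- length(r)
  fn <- function(par) {
    beta <- par[1:p] - par[(p + 1):(2 * p)]
    (1 - s) * as.numeric(t(beta) %*% R %*% beta) - 2 * sum(beta * r) +
      s * sum(beta^2) + 2 * lambda * sum(par)
  }
  best <- NULL
  set.seed(seed)
  starts <- c(list(rep(0, 2 * p)),
              replicate(n_starts - 1, abs(rnorm(2 * p, sd = 0.3)),
                        simplify = FALSE))
  for (st in starts) {
    o <- optim(st, fn, method = "L-BFGS-B", lower = 0,
               control = list(maxit = 2000, factr = 1e4))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best$par[1:p] - best$par[(p + 1):(2 * p)]
}

# Small score-tier cohort for fast tests.
tiny_cohort <- function(n = 1500, seed = 5, ...) {
  simulate_score_cohort(generator_config(n_individuals = n, seed = seed, ...))
}

# Small elastic-net tuning config for fast tests.
tiny_enet_config <- function(seed = 1, ...) {
  enet_config(alpha_grid = c(0.5, 1), n_lambda = 10, repeats = 2,
              k_folds = 5, seed = seed, ...)
}
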