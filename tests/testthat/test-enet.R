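test_that("unpenalized elastic net recovers ordinary least squares", {
  set.seed(1)
  x <- scale(matrix(rnorm(300 * 6), 300))
  colnames(x) <- paste0("v", 1:6)
  y <- rnorm(300); y <- y - mean(y)
  b <- enet_fit(x, y, alpha = 0.7, lambda = 0)
  expect_equal(unname(b), unname(qr.solve(x, y)), tolerance = 1e-8)
  expect_error(enet_fit(x, y, alpha = 1.2, lambda = 0.1),
               class = "polyenv_config_error")
})

test_that("lasso under an orthonormal design soft-thresholds the OLS solution", {
  set.seed(2)
  n <- 128
  q <- qr.Q(qr(matrix(rnorm(n * 5), n))) * sqrt(n)  # X'X/n = I
  y <- rnorm(n); y <- y - mean(y)
  ols <- as.numeric(crossprod(q, y) / n)
  for (lam in c(0.01, 0.05, 0.2)) {
    b <- enet_fit(q, y, alpha = 1, lambda = lam)
    expect_equal(unname(b), soft_threshold(ols, lam), tolerance = 1e-9)
  }
})

test_that("coordinate descent matches a brute-force minimizer on correlated designs", {
  set.seed(3)
  n <- 150
  z <- matrix(rnorm(n * 3), n)
  x <- scale(cbind(z[, 1], 0.8 * z[, 1] + 0.6 * z[, 2], z[, 3]))
  y <- as.numeric(x %*% c(1, -0.5, 0.2)) + rnorm(n)
  y <- y - mean(y)
  for (par in list(c(0.5, 0.1), c(1, 0.05), c(0.2, 0.3))) {
    mine <- enet_fit(x, y, par[1], par[2])
    oracle <- brute_enet(x, y, par[1], par[2])
    expect_equal(unname(mine), oracle, tolerance = 1e-6)
    # objective can only be at least as good as the oracle's
    expect_lte(enet_objective(x, y, mine, par[1], par[2]),
               enet_objective(x, y, oracle, par[1], par[2]) + 1e-10)
  }
})

test_that("solver agrees with an independent penalized-regression library", {
  skip_if_not_installed("glmnet")
  set.seed(4)
  x <- scale(matrix(rnorm(400 * 8), 400))
  colnames(x) <- paste0("v", 1:8)
  y <- as.numeric(x[, 1:3] %*% c(0.4, -0.3, 0.2)) + rnorm(400)
  y <- y - mean(y)
  for (par in list(c(1, 0.08), c(0.5, 0.05))) {
    g <- glmnet::glmnet(x, y, alpha = par[1], lambda = par[2],
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-14)
    mine <- enet_fit(x, y, par[1], par[2])
    # agreement up to the libraries' internal-scaling conventions, and our
    # solution is at least as good under the stated objective
    expect_equal(unname(mine), as.numeric(g$beta), tolerance = 5e-3)
    expect_lte(enet_objective(x, y, mine, par[1], par[2]),
               enet_objective(x, y, as.numeric(g$beta), par[1], par[2]) + 1e-10)
  }
})

test_that("sweeps are monotone in the objective and KKT holds at convergence", {
  set.seed(5)
  x <- scale(matrix(rnorm(200 * 10), 200))
  y <- as.numeric(x[, 1] * 0.5) + rnorm(200); y <- y - mean(y)
  alpha <- 0.8; lambda <- 0.06
  gram <- crossprod(x) / nrow(x)
  cty <- as.numeric(crossprod(x, y)) / nrow(x)
  beta <- numeric(10)
  objs <- enet_objective(x, y, beta, alpha, lambda)
  for (sweep in 1:25) {
    beta <- as.numeric(polyenv:::cd_enet_gram(gram, cty, lambda, alpha,
                                              beta, 0, 1L)$beta)
    objs <- c(objs, enet_objective(x, y, beta, alpha, lambda))
  }
  expect_true(all(diff(objs) <= 1e-12))
  b <- enet_fit(x, y, alpha, lambda)
  grad <- as.numeric(gram %*% b) - cty + lambda * (1 - alpha) * b
  active <- b != 0
  expect_lt(max(abs(grad[active] + lambda * alpha * sign(b[active])), 0), 1e-6)
  expect_lt(max(abs(grad[!active])), lambda * alpha + 1e-6)
})

test_that("repeated CV returns grid members and honours a single-point grid", {
  coh <- tiny_cohort(n = 300, seed = 6)
  panel <- prepare_panel(coh$data, coh$roles, seed = 6)
  tr <- polyenv:::panel_rows(panel, "train")
  one <- repeated_cv(tr$x, tr$y,
                     enet_config(alpha_grid = 0.5, n_lambda = 1,
                                 k_folds = 3, repeats = 1, seed = 6))
  expect_equal(nrow(one$cv_trace), 1L)
  expect_equal(one$alpha, 0.5)
  cfg <- enet_config(alpha_grid = c(0.3, 1), n_lambda = 5, k_folds = 3,
                     repeats = 2, seed = 6)
  res <- repeated_cv(tr$x, tr$y, cfg)
  expect_true(any(res$cv_trace$alpha == res$alpha &
                  abs(res$cv_trace$lambda - res$lambda) < 1e-12))
  expect_equal(min(res$cv_trace$rmse),
               res$cv_trace$rmse[res$cv_trace$alpha == res$alpha &
                                 res$cv_trace$lambda == res$lambda])
})

test_that("repeated CV equals an independent re-execution of the same loops", {
  set.seed(7)
  n <- 120
  x <- matrix(rnorm(n * 4), n); colnames(x) <- paste0("v", 1:4)
  y <- as.numeric(x[, 1] * 0.6) + rnorm(n)
  cfg <- enet_config(alpha_grid = c(0.4, 1), n_lambda = 3, k_folds = 2,
                     repeats = 2, seed = 99)
  res <- repeated_cv(x, y, cfg)

  # independent plain-loop recomputation with the same partition stream
  paths <- lapply(cfg$alpha_grid, function(a)
    polyenv:::enet_lambda_path(scale(x), y - mean(y), a, 3, 0.001))
  rmse <- matrix(0, 2, 3)
  set.seed(99)
  for (r in 1:2) {
    fold_id <- sample(rep_len(1:2, n))
    for (f in 1:2) {
      test <- fold_id == f
      xt <- scale(x[!test, ])
      xv <- sweep(sweep(x[test, ], 2, attr(xt, "scaled:center")), 2,
                  attr(xt, "scaled:scale"), "/")
      ybar <- mean(y[!test])
      for (ai in 1:2) for (li in 1:3) {
        b <- enet_fit(xt, y[!test] - ybar, cfg$alpha_grid[ai],
                      paths[[ai]][li], tol = 1e-7)
        pred <- as.numeric(xv %*% b) + ybar
        rmse[ai, li] <- rmse[ai, li] + sqrt(mean((y[test] - pred)^2))
      }
    }
  }
  rmse <- rmse / 4
  expect_equal(res$cv_trace$rmse, as.numeric(t(rmse)), tolerance = 1e-6)
  best <- arrayInd(which.min(t(rmse)), c(3, 2))
  expect_equal(res$lambda, paths[[best[2]]][best[1]], tolerance = 1e-12)
  expect_equal(res$alpha, cfg$alpha_grid[best[2]])
})

test_that("pure-noise outcomes select near-empty models", {
  empties <- sapply(1:8, function(s) {
    set.seed(s)
    x <- matrix(rnorm(600 * 20), 600)
    colnames(x) <- paste0("v", 1:20)
    y <- rnorm(600)
    cfg <- enet_config(alpha_grid = 1, n_lambda = 20, k_folds = 5,
                       repeats = 2, seed = s)
    tuned <- repeated_cv(x, y, cfg)
    b <- enet_fit(scale(x), y - mean(y), tuned$alpha, tuned$lambda)
    sum(b != 0)
  })
  expect_gte(mean(empties <= 1), 0.75)
})

test_that("hold-out evaluation implements 1 - SSE/SST", {
  fit <- structure(list(beta = c(v = 1), centers = c(v = 0), scales = c(v = 1),
                        y_center = 0), class = "polyenv_fit")
  # predictions equal to y give R2 = 1
  y <- c(1, 2, 3)
  perfect <- evaluate_holdout(fit, matrix(y, ncol = 1), y)
  expect_equal(perfect$r2, 1)
  # predictions at the hold-out mean give R2 = 0
  mean_fit <- structure(list(beta = c(v = 0), centers = c(v = 0),
                             scales = c(v = 1), y_center = mean(y)),
                        class = "polyenv_fit")
  expect_equal(evaluate_holdout(mean_fit, matrix(y, ncol = 1), y)$r2, 0)
  # hand arithmetic: y = (1,2,3), predictions (1,2,4)
  hand_fit <- structure(list(beta = c(v = 1), centers = c(v = 0),
                             scales = c(v = 1), y_center = 0),
                        class = "polyenv_fit")
  res <- evaluate_holdout(hand_fit, matrix(c(1, 2, 4), ncol = 1), y)
  expect_equal(res$sse, 1)
  expect_equal(res$sst, 2)
  expect_equal(res$r2, 0.5)
  expect_error(evaluate_holdout(fit, matrix(numeric(0), ncol = 1), numeric(0)),
               class = "polyenv_input_error")
})

test_that("variable importance rescales to 100 and keeps signs", {
  fit <- structure(list(beta = c(a = 0.4, b = -0.2, c = 0)),
                   class = "polyenv_fit")
  imp <- variable_importance(fit)
  expect_equal(imp$term, c("a", "b"))
  expect_equal(imp$importance, c(100, 50))
  expect_equal(imp$sign, c("+", "-"))
  single <- structure(list(beta = c(a = -3)), class = "polyenv_fit")
  expect_equal(variable_importance(single)$importance, 100)
  empty <- structure(list(beta = c(a = 0)), class = "polyenv_fit")
  expect_equal(nrow(variable_importance(empty)), 0L)
  # permuting predictors permutes importances identically
  fit2 <- structure(list(beta = fit$beta[c("b", "a", "c")]),
                    class = "polyenv_fit")
  imp2 <- variable_importance(fit2)
  expect_equal(dplyr::arrange(imp, term), dplyr::arrange(imp2, term))
})

test_that("the model driver selects role blocks and stores hold-out objects", {
  coh <- tiny_cohort(n = 400, seed = 14)
  panel <- prepare_panel(coh$data, coh$roles, seed = 14)
  fit_g <- fit_enet_model(panel, "G", tiny_enet_config(seed = 14))
  expect_equal(length(fit_g$beta), 20L)
  fit_e <- fit_enet_model(panel, "E", tiny_enet_config(seed = 14))
  expect_equal(length(fit_e$beta), 13L)
  expect_equal(length(fit_g$holdout_pred), sum(panel$split == "holdout"))
  expect_equal(fit_g$y_holdout, fit_e$y_holdout)
  expect_setequal(fit_g$active, names(fit_g$beta)[fit_g$beta != 0])
  expect_lte(fit_g$holdout$r2, 1)
})
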