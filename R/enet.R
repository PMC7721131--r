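#' Elastic-net configuration
#'
#' Tuning settings for the penalized prediction models: the alpha grid mixing
#' the L1 and L2 penalties, the lambda path specification, and the repeated
#' k-fold cross-validation layout (default 10-fold repeated 100 times,
#' minimizing RMSE).
#'
#' @param alpha_grid Values in \[0, 1\]; `alpha = 1` is the lasso, `alpha = 0`
#'   ridge.
#' @param n_lambda Number of lambda values per alpha, log-spaced from the
#'   smallest lambda that zeroes every coefficient down to
#'   `lambda_min_ratio` times it.
#' @param lambda_min_ratio Ratio of the smallest to largest lambda on the
#'   path (default 0.001).
#' @param k_folds Folds per repeat (default 10).
#' @param repeats Number of independent fold partitions (default 100).
#' @param seed Seed for the fold partitions.
#' @return An object of class `polyenv_enet_config`.
#' @export
enet_config <- function(alpha_grid = seq(0.1, 1, by = 0.1),
                        n_lambda = 100, lambda_min_ratio = 0.001,
                        k_folds = 10, repeats = 100, seed = 1) {
  if (length(alpha_grid) < 1 || any(alpha_grid < 0) || any(alpha_grid > 1)) {
    abort_polyenv("`alpha_grid` must be a non-empty set of values in [0, 1].",
                  class = "polyenv_config_error")
  }
  k_folds <- check_count(k_folds, "k_folds", min = 2L)
  repeats <- check_count(repeats, "repeats", min = 1L)
  n_lambda <- check_count(n_lambda, "n_lambda", min = 1L)
  check_scalar_number(lambda_min_ratio, "lambda_min_ratio", 1e-8, 1)
  structure(list(alpha_grid = sort(alpha_grid), n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio, k_folds = k_folds,
                 repeats = repeats, seed = seed),
            class = "polyenv_enet_config")
}

#' Elastic-net coefficients at fixed tuning
#'
#' Minimizes `(1/(2n)) ||y - X b||^2 + lambda * (alpha ||b||_1 +
#' ((1 - alpha)/2) ||b||_2^2)` by cyclic coordinate descent with
#' soft-thresholding on the Gram sufficient statistics. Columns of `x` are
#' expected standardized and `y` centered (no intercept is fit).
#'
#' @param x Predictor matrix.
#' @param y Response vector.
#' @param alpha Penalty mixing in \[0, 1\].
#' @param lambda Non-negative penalty strength (in the 1/(2n) scaling).
#' @param beta0 Optional warm start.
#' @param tol Convergence tolerance on the maximum coefficient change
#'   (default 1e-9).
#' @param maxit Maximum coordinate-descent sweeps.
#' @return Named numeric coefficient vector.
#' @export
enet_fit <- function(x, y, alpha, lambda, beta0 = NULL, tol = 1e-9,
                     maxit = 100000L) {
  check_scalar_number(alpha, "alpha", 0, 1)
  check_scalar_number(lambda, "lambda", 0)
  x <- as.matrix(x)
  n <- nrow(x)
  gram <- crossprod(x) / n
  cty <- as.numeric(crossprod(x, y)) / n
  if (is.null(beta0)) beta0 <- numeric(ncol(x))
  fit <- cd_enet_gram(gram, cty, lambda, alpha, beta0, tol, as.integer(maxit))
  setNames(as.numeric(fit$beta), colnames(x))
}

#' Elastic-net objective value
#'
#' The penalized loss minimized by [enet_fit()], exposed so that solver
#' output can be checked against independent minimizers.
#'
#' @inheritParams enet_fit
#' @param beta Coefficient vector.
#' @return Scalar objective value.
#' @export
enet_objective <- function(x, y, beta, alpha, lambda) {
  n <- nrow(as.matrix(x))
  r <- y - as.matrix(x) %*% beta
  sum(r^2) / (2 * n) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

enet_lambda_path <- function(x, y, alpha, n_lambda, lambda_min_ratio) {
  n <- nrow(x)
  lambda_max <- max(abs(crossprod(x, y))) / (n * max(alpha, 0.001))
  if (lambda_max <= 0) lambda_max <- 1e-3
  if (n_lambda == 1L) return(lambda_max)
  exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
          length.out = n_lambda))
}

#' Repeated k-fold cross-validation over the elastic-net grid
#'
#' For each repeat a fresh random fold partition is drawn; every
#' (alpha, lambda) grid point is fit on each training fold (standardization
#' refit within the fold, so no leakage) and scored by RMSE on the left-out
#' fold. The grid point with the smallest mean RMSE across all repeats and
#' folds is selected; exact ties go to the larger lambda, then the larger
#' alpha (the sparser model).
#'
#' @param x Training predictor matrix.
#' @param y Training response.
#' @param config An [enet_config()].
#' @return List with `alpha`, `lambda`, and `cv_trace` (tibble of
#'   `alpha`, `lambda`, `rmse` for the full grid).
#' @export
repeated_cv <- function(x, y, config = enet_config()) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- config$k_folds
  if (n < 2 * k) {
    abort_polyenv("too few rows for the requested fold count.",
                  class = "polyenv_input_error")
  }
  paths <- lapply(config$alpha_grid, function(a) {
    enet_lambda_path(scale(x), y - mean(y), a,
                     config$n_lambda, config$lambda_min_ratio)
  })
  grid <- dplyr::bind_rows(lapply(seq_along(config$alpha_grid), function(i) {
    tibble::tibble(alpha = config$alpha_grid[i], lambda = paths[[i]],
                   lambda_index = seq_along(paths[[i]]))
  }))
  rmse_sum <- numeric(nrow(grid))
  set.seed(config$seed)
  for (rep_i in seq_len(config$repeats)) {
    fold_id <- sample(rep_len(seq_len(k), n))
    for (fold in seq_len(k)) {
      test <- fold_id == fold
      if (sum(test) < 2 || sum(!test) < 2) {
        abort_polyenv("a cross-validation fold has fewer than 2 rows.",
                      class = "polyenv_input_error")
      }
      xt <- x[!test, , drop = FALSE]
      centers <- colMeans(xt)
      scales <- apply(xt, 2L, stats::sd)
      scales[scales < 1e-12] <- 1
      xt <- sweep(sweep(xt, 2L, centers, "-"), 2L, scales, "/")
      xv <- sweep(sweep(x[test, , drop = FALSE], 2L, centers, "-"),
                  2L, scales, "/")
      ybar <- mean(y[!test])
      yt <- y[!test] - ybar
      gram <- crossprod(xt) / nrow(xt)
      cty <- as.numeric(crossprod(xt, yt)) / nrow(xt)
      row_offset <- 0L
      for (i in seq_along(config$alpha_grid)) {
        a <- config$alpha_grid[i]
        beta <- numeric(ncol(x))
        for (li in seq_along(paths[[i]])) {
          sol <- cd_enet_gram(gram, cty, paths[[i]][li], a, beta, 1e-7, 10000L)
          beta <- as.numeric(sol$beta)
          pred <- as.numeric(xv %*% beta) + ybar
          rmse_sum[row_offset + li] <- rmse_sum[row_offset + li] +
            sqrt(mean((y[test] - pred)^2))
        }
        row_offset <- row_offset + length(paths[[i]])
      }
    }
  }
  grid$rmse <- rmse_sum / (config$repeats * k)
  ord <- order(grid$rmse, -grid$lambda, -grid$alpha)
  best <- grid[ord[1L], ]
  list(alpha = best$alpha, lambda = best$lambda,
       cv_trace = grid[c("alpha", "lambda", "rmse")])
}

#' Fit one of the penalized prediction models
#'
#' High-level driver: selects the predictor block by role (`"E"` =
#' environmental measures, `"G"` = polygenic scores, `"G+E"` = both), tunes
#' (alpha, lambda) by repeated cross-validation in the training rows, refits
#' on the full training set at the selected tuning, and evaluates hold-out
#' R-squared as `1 - SSE/SST`.
#'
#' @param panel A [prepare_panel()] result.
#' @param model One of `"E"`, `"G"`, `"G+E"`.
#' @param config An [enet_config()].
#' @param extra_columns Optional matrix of additional (already processed)
#'   columns appended to the design, e.g. GxE product terms; rows must align
#'   with the panel.
#' @return An object of class `polyenv_fit` with the chosen tuning,
#'   coefficients, active set, cross-validation trace and hold-out
#'   evaluation.
#' @export
fit_enet_model <- function(panel, model = c("G+E", "E", "G"),
                           config = enet_config(), extra_columns = NULL) {
  stopifnot(inherits(panel, "polyenv_panel"))
  model <- match.arg(model)
  roles <- switch(model, "E" = "environment", "G" = "gps",
                  "G+E" = c("gps", "environment"))
  keep_cols <- panel$roles$role %in% roles
  x_all <- panel$x[, keep_cols, drop = FALSE]
  if (!is.null(extra_columns)) {
    extra_columns <- as.matrix(extra_columns)
    stopifnot(nrow(extra_columns) == nrow(x_all))
    x_all <- cbind(x_all, extra_columns)
  }
  train <- panel$split == "train"
  x_train <- x_all[train, , drop = FALSE]
  y_train <- panel$y[train]
  tuned <- repeated_cv(x_train, y_train, config)

  centers <- colMeans(x_train)
  scales <- apply(x_train, 2L, stats::sd)
  scales[scales < 1e-12] <- 1
  xs <- sweep(sweep(x_train, 2L, centers, "-"), 2L, scales, "/")
  ybar <- mean(y_train)
  beta <- enet_fit(xs, y_train - ybar, tuned$alpha, tuned$lambda)

  fit <- structure(list(
    model = model, alpha = tuned$alpha, lambda = tuned$lambda,
    beta = beta, active = names(beta)[beta != 0],
    cv_trace = tuned$cv_trace,
    centers = centers, scales = scales, y_center = ybar,
    columns = colnames(x_all)
  ), class = "polyenv_fit")
  fit$holdout <- evaluate_holdout(fit, x_all[!train, , drop = FALSE],
                                  panel$y[!train])
  fit$holdout_pred <- predict(fit, x_all[!train, , drop = FALSE])
  fit$y_holdout <- panel$y[!train]
  fit
}

#' Predict from a fitted penalized model
#'
#' @param object A `polyenv_fit`.
#' @param newdata Matrix with the model's predictor columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.polyenv_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$beta)) {
    abort_polyenv("prediction matrix does not match the fitted coefficients.",
                  class = "polyenv_input_error")
  }
  xs <- sweep(sweep(newdata, 2L, object$centers, "-"), 2L, object$scales, "/")
  as.numeric(xs %*% object$beta) + object$y_center
}

#' Hold-out evaluation of a fitted model
#'
#' Computes `R^2 = 1 - SSE/SST` on the hold-out rows, with SST taken around
#' the hold-out outcome mean.
#'
#' @param fit A `polyenv_fit`.
#' @param x_holdout Hold-out predictor matrix.
#' @param y_holdout Hold-out outcome vector (non-empty).
#' @return A tibble with `r2`, `sse`, `sst`, `n_holdout`.
#' @export
evaluate_holdout <- function(fit, x_holdout, y_holdout) {
  if (length(y_holdout) == 0L) {
    abort_polyenv("empty hold-out set.", class = "polyenv_input_error")
  }
  pred <- predict(fit, x_holdout)
  sse <- sum((y_holdout - pred)^2)
  sst <- sum((y_holdout - mean(y_holdout))^2)
  tibble::tibble(r2 = 1 - sse / sst, sse = sse, sst = sst,
                 n_holdout = length(y_holdout))
}

#' Relative variable importance of a fitted model
#'
#' Importance is the absolute standardized coefficient rescaled so the
#' largest equals 100; the coefficient sign is retained separately for
#' display of trait-increasing versus trait-decreasing predictors.
#'
#' @param fit A `polyenv_fit`.
#' @return Tibble with `term`, `importance`, `sign`, ordered by decreasing
#'   importance. Empty when no predictor is active.
#' @export
variable_importance <- function(fit) {
  beta <- fit$beta[fit$beta != 0]
  if (length(beta) == 0L) {
    return(tibble::tibble(term = character(), importance = numeric(),
                          sign = character()))
  }
  tibble::tibble(
    term = names(beta),
    importance = unname(abs(beta) / max(abs(beta)) * 100),
    sign = unname(ifelse(beta > 0, "+", "-"))
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @export
print.polyenv_fit <- function(x, ...) {
  cat(sprintf("<polyenv_fit: %s model; alpha = %.2f, lambda = %.4g; %d/%d active; hold-out R2 = %.3f>\n",
              x$model, x$alpha, x$lambda, length(x$active), length(x$beta),
              x$holdout$r2))
  invisible(x)
}
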