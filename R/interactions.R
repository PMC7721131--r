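#' Enumerate candidate two-way interactions
#'
#' Builds all `p(p-1)/2` unordered predictor pairs and classifies each by
#' the roles of its members: `GxE` (one polygenic score, one environmental
#' measure), `GxG`, or `ExE`.
#'
#' @param roles Tibble with columns `column` and `role` (values `gps` /
#'   `environment`) for the candidate predictors, in panel order.
#' @return Object of class `polyenv_candidates`: tibble with `var1`, `var2`,
#'   `class`, one row per unordered pair.
#' @export
build_candidates <- function(roles) {
  roles <- tibble::as_tibble(roles)
  stopifnot(all(c("column", "role") %in% names(roles)))
  p <- nrow(roles)
  if (p < 2L) {
    abort_polyenv("at least two predictors are needed to form pairs.",
                  class = "polyenv_input_error")
  }
  idx <- utils::combn(p, 2L)
  cls <- function(r1, r2) {
    dplyr::case_when(
      r1 != r2 ~ "GxE",
      r1 == "gps" ~ "GxG",
      TRUE ~ "ExE"
    )
  }
  out <- tibble::tibble(
    var1 = roles$column[idx[1, ]],
    var2 = roles$column[idx[2, ]],
    class = cls(roles$role[idx[1, ]], roles$role[idx[2, ]])
  )
  class(out) <- c("polyenv_candidates", class(out))
  out
}

# Overlapped design for the hierarchical group lasso: main-effect columns
# first, then one 3-column block per candidate pair (the two member columns
# again, plus their re-standardized elementwise product).
interaction_design <- function(x, pairs) {
  x <- as.matrix(x)
  p <- ncol(x)
  q <- nrow(pairs)
  i1 <- match(pairs$var1, colnames(x))
  i2 <- match(pairs$var2, colnames(x))
  if (anyNA(i1) || anyNA(i2)) {
    abort_polyenv("candidate pair references a predictor absent from the panel.",
                  class = "polyenv_input_error")
  }
  z <- matrix(0, nrow(x), p + 3L * q)
  z[, seq_len(p)] <- x
  for (g in seq_len(q)) {
    off <- p + 3L * (g - 1L)
    prod_col <- x[, i1[g]] * x[, i2[g]]
    psd <- stats::sd(prod_col)
    if (psd < 1e-12) psd <- 1
    z[, off + 1L] <- x[, i1[g]]
    z[, off + 2L] <- x[, i2[g]]
    z[, off + 3L] <- (prod_col - mean(prod_col)) / psd
  }
  colnames(z) <- c(colnames(x),
                   unlist(lapply(seq_len(q), function(g) {
                     c(paste0(pairs$var1[g], ".m1.", g),
                       paste0(pairs$var2[g], ".m2.", g),
                       paste0(pairs$var1[g], ":", pairs$var2[g]))
                   })))
  list(z = z, p = p, q = q, i1 = i1, i2 = i2)
}

#' Hierarchical group-lasso objective
#'
#' The penalized loss of the overlapped-group interaction model:
#' `(1/(2n)) ||y - Z theta||^2 + lambda * (sum_j |beta_j| + w * sum_g
#' ||alpha_g||_2)`, where the mains `beta` are the first `p` entries of
#' `theta` and each candidate pair contributes a 3-coefficient group
#' (both member columns plus their product). Exposed for oracle tests.
#'
#' @param design Result of the internal interaction design builder (`z`,
#'   `p`, `q`).
#' @param y Centered outcome.
#' @param theta Full coefficient vector (length `p + 3q`).
#' @param lambda Penalty strength.
#' @param pair_weight Relative penalty weight of each pair group (default
#'   `sqrt(3)`, the square root of the group size).
#' @return Scalar objective value.
#' @export
hierarchical_objective <- function(design, y, theta, lambda,
                                   pair_weight = sqrt(3)) {
  n <- nrow(design$z)
  r <- y - design$z %*% theta
  pen_main <- sum(abs(theta[seq_len(design$p)]))
  pen_grp <- 0
  if (design$q > 0) {
    a <- matrix(theta[-seq_len(design$p)], nrow = 3L)
    pen_grp <- sum(sqrt(colSums(a^2)))
  }
  sum(r^2) / (2 * n) + lambda * (pen_main + pair_weight * pen_grp)
}

# Proximal operator of the penalty: soft-threshold the mains, group
# soft-threshold each 3-coefficient pair block.
hier_prox <- function(theta, p, thr_main, thr_grp) {
  theta[seq_len(p)] <- soft_threshold(theta[seq_len(p)], thr_main)
  if (length(theta) > p) {
    a <- matrix(theta[-seq_len(p)], nrow = 3L)
    norms <- sqrt(colSums(a^2))
    shrink <- pmax(0, 1 - thr_grp / pmax(norms, 1e-300))
    theta[-seq_len(p)] <- as.numeric(a * rep(shrink, each = 3L))
  }
  theta
}

# Karush-Kuhn-Tucker residual of the group-lasso objective: the largest
# violation of the stationarity conditions. Zero at (and only at) a global
# minimizer of the convex objective.
hier_kkt_residual <- function(gram, zy, theta, p, lambda, pair_weight) {
  grad <- as.numeric(gram %*% theta) - zy
  b <- theta[seq_len(p)]
  res <- 0
  active <- abs(b) > 0
  if (any(active)) {
    res <- max(res, abs(grad[seq_len(p)][active] + lambda * sign(b[active])))
  }
  if (any(!active)) {
    res <- max(res, max(0, abs(grad[seq_len(p)][!active]) - lambda))
  }
  if (length(theta) > p) {
    a <- matrix(theta[-seq_len(p)], nrow = 3L)
    ga <- matrix(grad[-seq_len(p)], nrow = 3L)
    norms <- sqrt(colSums(a^2))
    on <- norms > 0
    if (any(on)) {
      stat <- ga[, on, drop = FALSE] +
        lambda * pair_weight * a[, on, drop = FALSE] /
          rep(norms[on], each = 3L)
      res <- max(res, max(abs(stat)))
    }
    if (any(!on)) {
      gn <- sqrt(colSums(ga[, !on, drop = FALSE]^2))
      res <- max(res, max(0, gn - lambda * pair_weight))
    }
  }
  res
}

# Monotone FISTA for one lambda, on Gram sufficient statistics. `tol` is the
# KKT-residual tolerance, checked periodically.
hier_fista <- function(gram, zy, yty_n, n, p, lambda, pair_weight, step,
                       theta0, tol = 1e-7, maxit = 5000L) {
  obj <- function(th) {
    pen_main <- sum(abs(th[seq_len(p)]))
    pen_grp <- if (length(th) > p) {
      a <- matrix(th[-seq_len(p)], nrow = 3L)
      sum(sqrt(colSums(a^2)))
    } else 0
    0.5 * yty_n - sum(th * zy) + 0.5 * sum(th * (gram %*% th)) +
      lambda * (pen_main + pair_weight * pen_grp)
  }
  x_prev <- theta0
  v <- theta0
  t_k <- 1
  f_prev <- obj(x_prev)
  trace <- f_prev
  for (it in seq_len(maxit)) {
    grad <- as.numeric(gram %*% v) - zy
    z_k <- hier_prox(v - step * grad, p, step * lambda,
                     step * lambda * pair_weight)
    f_z <- obj(z_k)
    if (f_z <= f_prev) {
      x_new <- z_k; f_new <- f_z
    } else {
      x_new <- x_prev; f_new <- f_prev
    }
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    v <- x_new + (t_k / t_next) * (z_k - x_new) +
      ((t_k - 1) / t_next) * (x_new - x_prev)
    x_prev <- x_new; f_prev <- f_new; t_k <- t_next
    trace <- c(trace, f_new)
    if (it %% 10L == 0L &&
        hier_kkt_residual(gram, zy, x_prev, p, lambda, pair_weight) < tol) {
      break
    }
  }
  list(theta = x_prev, objective = f_prev, trace = trace)
}

#' Discover two-way interactions under strong hierarchy
#'
#' Fits the overlapped group-lasso interaction model (each candidate pair
#' contributes a group holding both main-effect columns and the product
#' term) along a decreasing lambda path by monotone proximal gradient
#' descent, selecting lambda by k-fold cross-validation. Because a pair can
#' enter only through a group that also carries its two main effects, every
#' selected interaction automatically satisfies strong hierarchy: both of
#' its members are selected as main effects.
#'
#' @param x Standardized predictor matrix with column names.
#' @param y Continuous outcome.
#' @param roles Optional roles tibble for pair classification (defaults to
#'   all-`environment`, giving class `ExE`).
#' @param n_lambda,lambda_min_ratio Path specification (log-spaced from the
#'   smallest all-zero lambda).
#' @param cv_folds Folds for lambda selection (default 10).
#' @param seed Seed for the fold partition.
#' @param pair_weight Penalty weight of pair groups relative to mains
#'   (default `sqrt(3)`, the square-root-of-group-size scaling).
#' @param rule Lambda-selection rule: `"1se"` (largest lambda within one
#'   standard error of the minimum cross-validated MSE; the conservative
#'   default, favouring sparser interaction sets) or `"min"`.
#' @param tol Solver stopping tolerance on the KKT stationarity residual.
#' @param maxit Maximum proximal-gradient iterations per lambda.
#' @param cv_tol,cv_maxit Relaxed solver controls used for the
#'   cross-validation path fits (lambda selection needs far less precision
#'   than the final fit; defaults 1e-5 and 1000).
#' @return Object of class `polyenv_selection`: tibbles `mains` (term,
#'   coefficient, selected) and `pairs` (var1, var2, class, weight — the
#'   selected pairs), the chosen `lambda`, the `cv` trace, and the full
#'   coefficient vector.
#' @export
fit_hierarchical <- function(x, y, roles = NULL, n_lambda = 20,
                             lambda_min_ratio = 0.01, cv_folds = 10, seed = 1,
                             pair_weight = sqrt(3), rule = c("1se", "min"),
                             tol = 1e-7, maxit = 5000L,
                             cv_tol = max(tol, 1e-5), cv_maxit = min(maxit, 1000L)) {
  rule <- match.arg(rule)
  x <- as.matrix(x)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort_polyenv("non-finite values in the inputs.", class = "polyenv_input_error")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (is.null(roles)) {
    roles <- tibble::tibble(column = colnames(x), role = "environment")
  }
  candidates <- build_candidates(roles[match(colnames(x), roles$column), ])
  design <- interaction_design(x, candidates)
  n <- nrow(x)
  ybar <- mean(y)
  yc <- y - ybar

  gram_full <- crossprod(design$z) / n
  zy_full <- as.numeric(crossprod(design$z, yc)) / n
  group_norm <- function(v) {
    a <- matrix(v[-seq_len(design$p)], nrow = 3L)
    sqrt(colSums(a^2))
  }
  lambda_max <- max(max(abs(zy_full[seq_len(design$p)])),
                    max(group_norm(zy_full)) / pair_weight)
  if (!is.finite(lambda_max) || lambda_max <= 0) lambda_max <- 1e-3
  lambda_path <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                         length.out = n_lambda))
  step_full <- 1 / power_iter_maxeig(gram_full)

  cv_fold_mse <- matrix(NA_real_, cv_folds, n_lambda)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(cv_folds), n))
  for (fold in seq_len(cv_folds)) {
    test <- fold_id == fold
    zt <- design$z[!test, , drop = FALSE]
    nt <- nrow(zt)
    ybar_t <- mean(y[!test])
    yt <- y[!test] - ybar_t
    gram <- crossprod(zt) / nt
    zy <- as.numeric(crossprod(zt, yt)) / nt
    yty_n <- sum(yt^2) / nt
    step <- 1 / power_iter_maxeig(gram)
    theta <- numeric(ncol(design$z))
    for (li in seq_len(n_lambda)) {
      sol <- hier_fista(gram, zy, yty_n, nt, design$p, lambda_path[li],
                        pair_weight, step, theta, cv_tol, cv_maxit)
      theta <- sol$theta
      pred <- as.numeric(design$z[test, , drop = FALSE] %*% theta) + ybar_t
      cv_fold_mse[fold, li] <- mean((y[test] - pred)^2)
    }
  }
  cv_mse <- colMeans(cv_fold_mse)
  cv_se <- apply(cv_fold_mse, 2L, stats::sd) / sqrt(cv_folds)
  min_li <- which.min(cv_mse)
  best_li <- if (rule == "min") min_li else
    which(cv_mse <= cv_mse[min_li] + cv_se[min_li])[1L]  # path is decreasing
  lambda <- lambda_path[best_li]

  yty_n <- sum(yc^2) / n
  theta <- numeric(ncol(design$z))
  final <- NULL
  for (li in seq_len(best_li)) {
    final <- hier_fista(gram_full, zy_full, yty_n, n, design$p,
                        lambda_path[li], pair_weight, step_full, theta,
                        tol, maxit)
    theta <- final$theta
  }

  p <- design$p
  pair_norms <- group_norm(theta)
  sel_pairs <- which(pair_norms > 1e-8)
  # total main effect = dedicated main coefficient + contributions from
  # every group in which the predictor appears
  main_total <- theta[seq_len(p)]
  if (design$q > 0) {
    a <- matrix(theta[-seq_len(p)], nrow = 3L)
    for (g in seq_len(design$q)) {
      main_total[design$i1[g]] <- main_total[design$i1[g]] + a[1, g]
      main_total[design$i2[g]] <- main_total[design$i2[g]] + a[2, g]
    }
  }
  selected_main <- abs(main_total) > 1e-8
  if (length(sel_pairs) > 0) {
    selected_main[unique(c(design$i1[sel_pairs], design$i2[sel_pairs]))] <- TRUE
  }
  pairs_out <- candidates[sel_pairs, , drop = FALSE]
  pairs_out$weight <- pair_norms[sel_pairs]
  structure(list(
    mains = tibble::tibble(term = colnames(x), coefficient = main_total,
                           selected = selected_main),
    pairs = tibble::as_tibble(pairs_out),
    candidates = tibble::as_tibble(candidates)[c("var1", "var2", "class")],
    lambda = lambda, lambda_path = lambda_path, rule = rule,
    cv = tibble::tibble(lambda = lambda_path, mse = cv_mse, se = cv_se),
    pair_weight = pair_weight, theta = theta,
    objective = if (is.null(final)) NA_real_ else final$objective,
    objective_trace = if (is.null(final)) numeric(0) else final$trace
  ), class = "polyenv_selection")
}

power_iter_maxeig <- function(gram, iter = 100L) {
  v <- rep(1, ncol(gram)) / sqrt(ncol(gram))
  ev <- 1
  for (i in seq_len(iter)) {
    w <- as.numeric(gram %*% v)
    ev <- sqrt(sum(w^2))
    if (ev < 1e-300) return(1e-12)
    v <- w / ev
  }
  ev * 1.01  # small safety margin on the Lipschitz constant
}

#' @export
print.polyenv_selection <- function(x, ...) {
  cat(sprintf("<polyenv_selection: %d/%d mains, %d pairs (%s) at lambda = %.4g>\n",
              sum(x$mains$selected), nrow(x$mains), nrow(x$pairs),
              paste(sprintf("%s: %d", names(table(x$pairs$class)),
                            table(x$pairs$class)), collapse = ", "),
              x$lambda))
  invisible(x)
}

#' Refit the joint model with discovered GxE interaction terms
#'
#' Augments the G+E design with the elementwise products of the selected
#' gene-environment pairs (products of standardized columns,
#' re-standardized) and refits the elastic net with the same tuning
#' machinery, evaluating hold-out R-squared. Comparison against the additive
#' G+E model is done with [bootstrap_r2()].
#'
#' @param panel A [prepare_panel()] result.
#' @param gxe_pairs Tibble with columns `var1`, `var2` (and optionally
#'   `class`, which must then be `"GxE"`), e.g. the `pairs` element of a
#'   [fit_hierarchical()] filtered to GxE.
#' @param config An [enet_config()].
#' @return A `polyenv_fit` labelled `"G*E"`.
#' @export
refit_with_gxe <- function(panel, gxe_pairs, config = enet_config()) {
  stopifnot(inherits(panel, "polyenv_panel"))
  gxe_pairs <- tibble::as_tibble(gxe_pairs)
  extra <- NULL
  if (nrow(gxe_pairs) > 0) {
    if ("class" %in% names(gxe_pairs) && !all(gxe_pairs$class == "GxE")) {
      abort_polyenv("only GxE-classified pairs can be reintroduced.",
                    class = "polyenv_input_error")
    }
    missing_vars <- setdiff(c(gxe_pairs$var1, gxe_pairs$var2), colnames(panel$x))
    if (length(missing_vars) > 0) {
      abort_polyenv(sprintf("pair references predictor(s) absent from the panel: %s",
                            paste(missing_vars, collapse = ", ")),
                    class = "polyenv_input_error")
    }
    extra <- sapply(seq_len(nrow(gxe_pairs)), function(i) {
      as.numeric(scale(panel$x[, gxe_pairs$var1[i]] * panel$x[, gxe_pairs$var2[i]]))
    })
    colnames(extra) <- paste0(gxe_pairs$var1, ":", gxe_pairs$var2)
  }
  fit <- fit_enet_model(panel, "G+E", config, extra_columns = extra)
  if (!is.null(extra)) fit$model <- "G*E"
  fit
}
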