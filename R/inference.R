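# Post-selection inference: naive / hold-out OLS and conditional (selective)
# inference for the predictors selected by an L1-penalized fit, via the
# polyhedral characterization of the selection event and the resulting
# truncated normal distribution of each partial regression coefficient.

ols_table <- function(x, y, terms, method) {
  x <- as.matrix(x)[, terms, drop = FALSE]
  if (length(y) == 0L) {
    abort_polyenv("empty sample for OLS estimation.", class = "polyenv_input_error")
  }
  d <- cbind(`(Intercept)` = 1, x)
  qd <- qr(d)
  if (qd$rank < ncol(d)) {
    piv <- qd$pivot[seq_len(qd$rank)]
    bad <- setdiff(colnames(d), colnames(d)[piv])
    abort_polyenv(sprintf("design is rank deficient; collinear column(s): %s",
                          paste(bad, collapse = ", ")),
                  class = "polyenv_input_error")
  }
  fit <- lm.fit(d, y)
  df <- length(y) - ncol(d)
  sigma2 <- sum(fit$residuals^2) / df
  xtxinv <- chol2inv(qr.R(qd))
  se <- sqrt(sigma2 * diag(xtxinv))
  est <- fit$coefficients
  stat <- est / se
  p <- 2 * stats::pt(-abs(stat), df)
  ci <- stats::qt(0.975, df) * se
  tibble::tibble(term = colnames(d), estimate = unname(est),
                 std_error = unname(se), statistic = unname(stat),
                 p_value = unname(p),
                 conf_low = unname(est - ci), conf_high = unname(est + ci),
                 method = method)[-1L, ]
}

#' Naive training-set OLS for the selected predictors
#'
#' Refits the active set of a penalized model by multiple regression in the
#' training rows — the estimates whose p-values are over-optimistic because
#' the same data chose the predictors.
#'
#' @param panel A [prepare_panel()] result.
#' @param active Character vector of selected predictor names (non-empty).
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`, `conf_low`, `conf_high`, `method = "naive"`.
#' @export
naive_ols <- function(panel, active) {
  if (length(active) == 0L) {
    abort_polyenv("the active set is empty.", class = "polyenv_input_error")
  }
  tr <- panel_rows(panel, "train")
  ols_table(tr$x, tr$y, active, "naive")
}

#' Hold-out OLS for the selected predictors
#'
#' As [naive_ols()] but estimated on the hold-out rows, which were not used
#' for selection; valid but typically wider intervals (smaller sample).
#'
#' @inheritParams naive_ols
#' @return Tibble as in [naive_ols()], with `method = "holdout"`.
#' @export
holdout_ols <- function(panel, active) {
  if (length(active) == 0L) {
    abort_polyenv("the active set is empty.", class = "polyenv_input_error")
  }
  ho <- panel_rows(panel, "holdout")
  if (nrow(ho$x) == 0L) {
    abort_polyenv("empty hold-out set.", class = "polyenv_input_error")
  }
  ols_table(ho$x, ho$y, active, "holdout")
}

# Stable CDF of N(mu, tau^2) truncated to [a, b], evaluated at z, computed
# through log tail probabilities so extreme truncation bounds do not
# underflow.
ptruncnorm <- function(z, a, b, mu, tau) {
  za <- (a - mu) / tau; zb <- (b - mu) / tau; zz <- (z - mu) / tau
  zz <- min(max(zz, za), zb)
  logdiff <- function(lo, hi) {
    # log( Phi(hi) - Phi(lo) ) using whichever tail is better conditioned
    mid <- lo + hi
    if (is.nan(mid)) mid <- 0  # doubly infinite interval
    if (mid > 0) {
      lu <- pnorm(lo, lower.tail = FALSE, log.p = TRUE)
      lv <- pnorm(hi, lower.tail = FALSE, log.p = TRUE)
    } else {
      lu <- pnorm(hi, log.p = TRUE)
      lv <- pnorm(lo, log.p = TRUE)
    }
    if (lv >= lu) return(-Inf)
    lu + log1p(-exp(lv - lu))
  }
  ln <- logdiff(za, zz)
  ld <- logdiff(za, zb)
  if (!is.finite(ld)) return(NA_real_)
  exp(ln - ld)
}

# Polyhedral representation {Ay <= b} of the event that an L1-penalized
# regression (lasso component lam1, optional ridge component lam2, in the
# 1/(2n) loss scaling) selects exactly `active` with signs `signs`.
selection_polyhedron <- function(x, active, signs, lam1, lam2 = 0) {
  n <- nrow(x)
  xa <- x[, active, drop = FALSE]
  xi <- x[, setdiff(colnames(x), active), drop = FALSE]
  k <- crossprod(xa) / n + diag(lam2, ncol(xa))
  kinv <- solve(k)
  # sign consistency of the active coefficients
  a1 <- -(signs * kinv) %*% t(xa) / n
  b1 <- -lam1 * as.numeric((signs * kinv) %*% signs)
  amat <- a1; bvec <- b1
  if (ncol(xi) > 0) {
    h <- t(xi) %*% (diag(n) - xa %*% kinv %*% t(xa) / n) / n
    c0 <- lam1 * as.numeric(t(xi) %*% xa %*% kinv %*% signs) / n
    amat <- rbind(amat, h, -h)
    bvec <- c(bvec, lam1 - c0, lam1 + c0)
  }
  list(amat = amat, bvec = bvec)
}

#' Conditional (selective) inference for an L1-selected active set
#'
#' For each selected predictor, characterizes the selection event of the
#' penalized fit as a polyhedron in outcome space, derives the truncation
#' interval \[a, b\] of the predictor's partial regression coefficient, and
#' returns the p-value and confidence interval of the coefficient under its
#' truncated normal distribution `TN_[a,b](beta, tau^2)`. When the selection
#' constraint is non-binding (`a = -Inf`, `b = Inf`) the conditional p-value
#' reduces to the naive normal p-value. Elastic-net selection (`alpha < 1`)
#' is handled by absorbing the ridge component into the selection event
#' (lasso-on-augmented-data reduction), which is an approximation documented
#' in the methods vignette.
#'
#' @param x_train Standardized training predictor matrix (all candidates).
#' @param y_train Centered training outcome.
#' @param lambda Penalty strength of the fit, in the 1/(2n) scaling.
#' @param active Character vector of selected predictor names.
#' @param signs Signs (+1/-1) of the selected coefficients.
#' @param alpha Elastic-net mixing of the selecting fit (1 = lasso).
#' @param sigma Noise standard deviation; if `NULL`, estimated from the
#'   residuals of the selected-model OLS in the training rows.
#' @param level Confidence level for the conditional intervals.
#' @return Tibble with one row per active predictor: `term`, `estimate` (the
#'   selected-model OLS coefficient), `tau` (its standard deviation), `a`,
#'   `b` (truncation bounds), `p_value`, `conf_low`, `conf_high`,
#'   `method = "conditional"`. Degenerate truncation (observed value at a
#'   boundary) yields an infinite interval and `p_value = NA`, flagged in
#'   the `degenerate` column, rather than an error.
#' @export
selective_inference <- function(x_train, y_train, lambda, active, signs,
                                alpha = 1, sigma = NULL, level = 0.95) {
  x <- as.matrix(x_train)
  if (length(active) == 0L) {
    abort_polyenv("the active set is empty.", class = "polyenv_input_error")
  }
  lam1 <- lambda * alpha
  lam2 <- lambda * (1 - alpha)
  poly <- selection_polyhedron(x, active, signs, lam1, lam2)
  xa <- x[, active, drop = FALSE]
  xtxinv <- solve(crossprod(xa))
  if (is.null(sigma)) {
    res <- y_train - xa %*% xtxinv %*% crossprod(xa, y_train)
    df <- length(y_train) - length(active)
    sigma <- sqrt(sum(res^2) / df)
  }
  alpha_lvl <- 1 - level
  rows <- lapply(seq_along(active), function(j) {
    eta <- as.numeric(xa %*% xtxinv[, j])
    z <- sum(eta * y_train)
    tau <- sigma * sqrt(sum(eta^2))
    cvec <- eta / sum(eta^2)
    w <- y_train - cvec * z
    rho <- as.numeric(poly$amat %*% cvec)
    u <- poly$bvec - as.numeric(poly$amat %*% w)
    vlo <- suppressWarnings(max((u / rho)[rho < -1e-12], -Inf))
    vup <- suppressWarnings(min((u / rho)[rho > 1e-12], Inf))
    degenerate <- !(vlo - 1e-8 <= z && z <= vup + 1e-8) || vlo >= vup
    if (degenerate) {
      return(tibble::tibble(term = active[j], estimate = z, tau = tau,
                            a = vlo, b = vup, p_value = NA_real_,
                            conf_low = -Inf, conf_high = Inf,
                            method = "conditional", degenerate = TRUE))
    }
    f0 <- ptruncnorm(z, vlo, vup, 0, tau)
    p <- if (is.na(f0)) NA_real_ else 2 * min(f0, 1 - f0)
    ci <- tn_confint(z, vlo, vup, tau, alpha_lvl)
    tibble::tibble(term = active[j], estimate = z, tau = tau,
                   a = vlo, b = vup, p_value = p,
                   conf_low = ci[1], conf_high = ci[2],
                   method = "conditional", degenerate = FALSE)
  })
  dplyr::bind_rows(rows)
}

# Invert the truncated-normal CDF in its mean to get a conditional interval:
# F_mu(z) is decreasing in mu, so the endpoints solve F_mu(z) = 1 - a/2 and
# F_mu(z) = a/2.
tn_confint <- function(z, vlo, vup, tau, alpha_lvl) {
  fmu <- function(mu) ptruncnorm(z, vlo, vup, mu, tau)
  solve_for <- function(target) {
    lo <- z - 30 * tau; hi <- z + 30 * tau
    flo <- fmu(lo); fhi <- fmu(hi)
    if (is.na(flo) || is.na(fhi) || (flo - target) * (fhi - target) > 0) {
      return(NA_real_)
    }
    stats::uniroot(function(mu) fmu(mu) - target, c(lo, hi),
                   tol = 1e-8 * max(tau, 1))$root
  }
  lower <- solve_for(1 - alpha_lvl / 2)
  upper <- solve_for(alpha_lvl / 2)
  c(ifelse(is.na(lower), -Inf, lower), ifelse(is.na(upper), Inf, upper))
}

#' Post-selection estimates for a fitted penalized model
#'
#' Convenience wrapper producing the three estimate sets compared in the
#' pipeline for one fitted model: naive training-set OLS, hold-out OLS, and
#' conditional truncated-normal inference at the fit's own penalty.
#'
#' @param fit A `polyenv_fit` with a non-empty active set.
#' @param panel The [prepare_panel()] the model was fit on.
#' @param methods Subset of `c("naive", "holdout", "conditional")`.
#' @return Tibble of stacked estimate tables with a `method` column.
#' @export
postselection_estimates <- function(fit, panel,
                                    methods = c("naive", "holdout", "conditional")) {
  active <- fit$active
  if (length(active) == 0L) {
    abort_polyenv("the fitted model selected no predictors.",
                  class = "polyenv_input_error")
  }
  out <- list()
  if ("naive" %in% methods) out$naive <- naive_ols(panel, active)
  if ("holdout" %in% methods) out$holdout <- holdout_ols(panel, active)
  if ("conditional" %in% methods) {
    tr <- panel_rows(panel, "train")
    x <- tr$x[, fit$columns[fit$columns %in% colnames(tr$x)], drop = FALSE]
    cond <- selective_inference(
      scale(x), tr$y - mean(tr$y), fit$lambda, active,
      signs = sign(fit$beta[active]), alpha = fit$alpha)
    out$conditional <- cond[c("term", "estimate", "a", "b", "p_value",
                              "conf_low", "conf_high", "method")]
  }
  dplyr::bind_rows(out)
}
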