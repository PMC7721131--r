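#' Hold-out composite pair for rGE analysis
#'
#' Collects the hold-out predicted outcome values from the genetic model
#' (`g_ea`) and the environmental model (`e_ea`) together with the observed
#' hold-out outcome; the correlation of the two prediction composites is the
#' operational measure of gene-environment correlation.
#'
#' @param g_fit,e_fit `polyenv_fit` objects for the G-only and E-only models,
#'   sharing the same hold-out rows.
#' @param outcome Optional hold-out outcome (defaults to the outcome stored
#'   in `g_fit`).
#' @return Object of class `polyenv_composites` (list `g_ea`, `e_ea`,
#'   `outcome`).
#' @export
composite_pair <- function(g_fit, e_fit, outcome = NULL) {
  g_ea <- g_fit$holdout_pred
  e_ea <- e_fit$holdout_pred
  if (is.null(outcome)) outcome <- g_fit$y_holdout
  if (length(g_ea) != length(e_ea) || length(g_ea) != length(outcome)) {
    abort_polyenv("composites and outcome must have equal length (same hold-out rows).",
                  class = "polyenv_input_error")
  }
  structure(list(g_ea = g_ea, e_ea = e_ea, outcome = outcome),
            class = "polyenv_composites")
}

#' Gene-environment correlation of prediction composites
#'
#' Pearson correlation `r_GE = cor(g_ea, e_ea)` of the hold-out predicted
#' values from the genetic and environmental models, with a paired percentile
#' bootstrap confidence interval.
#'
#' @param pair A [composite_pair()], or any list with numeric `g_ea` and
#'   `e_ea` of equal length.
#' @param B Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return Tibble with `estimate`, `lower`, `upper`, `n`, `B`.
#' @export
rge_correlation <- function(pair, B = 1000, seed = 1, level = 0.95) {
  g <- pair$g_ea; e <- pair$e_ea
  if (stats::sd(g) < 1e-12 || stats::sd(e) < 1e-12) {
    abort_polyenv("a composite has zero variance; correlation undefined.",
                  class = "polyenv_zero_variance_error")
  }
  B <- check_count(B, "B", min = 2L)
  est <- cor(g, e)
  set.seed(seed)
  n <- length(g)
  draws <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    suppressWarnings(cor(g[idx], e[idx]))
  }, numeric(1))
  ci <- percentile_ci(draws, level)
  tibble::tibble(estimate = est, lower = ci[1], upper = ci[2], n = n, B = B)
}

# Path coefficients of the linear mediation triangle on a fixed dataset.
mediation_paths <- function(x, m, y) {
  cfit1 <- lm.fit(cbind(1, x), y)$coefficients
  cfit2 <- lm.fit(cbind(1, x, m), y)$coefficients
  afit <- lm.fit(cbind(1, x), m)$coefficients
  c(beta_c = unname(cfit1[2]), beta_c_prime = unname(cfit2[2]),
    beta_b = unname(cfit2[3]), beta_a = unname(afit[2]))
}

#' Arithmetic of the mediated-effect decomposition
#'
#' Given a total effect and the direct effect after adjusting for the
#' mediator, returns the indirect (mediated) effect `beta_c - beta_c_prime`
#' and the proportion mediated `(beta_c - beta_c_prime) / beta_c` (undefined
#' when the total effect is below tolerance).
#'
#' @param beta_c Total effect of the predictor on the outcome.
#' @param beta_c_prime Direct effect after adjusting for the mediator.
#' @param tol Tolerance below which the proportion is undefined.
#' @return Tibble with `indirect` and `proportion_mediated`.
#' @export
mediation_decomposition <- function(beta_c, beta_c_prime, tol = 1e-8) {
  indirect <- unname(beta_c - beta_c_prime)
  tibble::tibble(
    indirect = indirect,
    proportion_mediated = unname(ifelse(abs(beta_c) > tol,
                                        indirect / unname(beta_c), NA_real_))
  )
}

#' Linear mediation analysis with bootstrap confidence intervals
#'
#' Fits the three linear regressions of the mediation triangle — `y ~ x`
#' (total effect `beta_c`), `y ~ x + m` (direct effect `beta_c_prime` and
#' mediator path `beta_b`), `m ~ x` (`beta_a`) — and decomposes the total
#' effect into direct and indirect parts. In this saturated linear model the
#' difference of coefficients equals the product of coefficients
#' (`beta_c - beta_c_prime = beta_a * beta_b`) on any fixed dataset.
#' Percentile bootstrap intervals refit all paths on each resample.
#'
#' @param x Predictor vector.
#' @param m Mediator vector.
#' @param y Outcome vector.
#' @param B Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @param orientation Label recorded with the result.
#' @return Object of class `polyenv_mediation`: tibble `estimates` (`term`,
#'   `estimate`, `lower`, `upper`) covering all paths, the indirect effect
#'   and the proportion mediated (undefined when `|beta_c|` is below
#'   tolerance), plus the raw bootstrap draws.
#' @export
mediate <- function(x, m, y, B = 1000, seed = 1, level = 0.95,
                    orientation = "X_via_M") {
  stopifnot(length(x) == length(m), length(m) == length(y))
  B <- check_count(B, "B", min = 2L)
  paths <- mediation_paths(x, m, y)
  dec <- mediation_decomposition(paths["beta_c"], paths["beta_c_prime"])
  point <- c(paths, indirect = dec$indirect,
             proportion_mediated = dec$proportion_mediated)
  set.seed(seed)
  n <- length(x)
  draws <- matrix(NA_real_, B, length(point),
                  dimnames = list(NULL, names(point)))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    p <- mediation_paths(x[idx], m[idx], y[idx])
    d <- mediation_decomposition(p["beta_c"], p["beta_c_prime"])
    draws[b, ] <- c(p, d$indirect, d$proportion_mediated)
  }
  est <- purrr::map_dfr(names(point), function(t) {
    ci <- percentile_ci(draws[, t], level)
    tibble::tibble(term = t, estimate = unname(point[t]),
                   lower = ci[1], upper = ci[2])
  })
  structure(list(estimates = est, draws = draws, orientation = orientation,
                 B = B, level = level),
            class = "polyenv_mediation")
}

#' Reciprocal mediation of the two prediction composites
#'
#' Runs the mediation model in both orientations on a hold-out composite
#' pair: (1) the environmental composite mediating the genetic effect on the
#' outcome (environmental mediation of G), and (2) the genetic composite
#' mediating the environmental effect (statistically a mediation model,
#' interpreted as genetic confounding — the two are equivalent in the linear
#' case but conceptually distinct).
#'
#' @param pair A [composite_pair()].
#' @param B,seed,level Passed to [mediate()].
#' @return Named list of two `polyenv_mediation` results: `G_via_E` and
#'   `E_via_G`.
#' @export
run_both_orientations <- function(pair, B = 1000, seed = 1, level = 0.95) {
  z <- function(v) as.numeric(scale(v))
  g <- z(pair$g_ea); e <- z(pair$e_ea); y <- z(pair$outcome)
  list(
    G_via_E = mediate(g, e, y, B = B, seed = seed, level = level,
                      orientation = "G_via_E"),
    E_via_G = mediate(e, g, y, B = B, seed = seed, level = level,
                      orientation = "E_via_G")
  )
}

#' @export
print.polyenv_mediation <- function(x, ...) {
  cat(sprintf("<polyenv_mediation: %s, B = %d>\n", x$orientation, x$B))
  print(x$estimates)
  invisible(x)
}
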