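#' Bootstrap hold-out R-squared and nested-model differences
#'
#' Draws `B` resamples of the hold-out rows with replacement — the *same* row
#' indices for every model, so the per-resample R-squared values are paired —
#' and recomputes `R^2 = 1 - SSE/SST` per model and per draw. The fitted
#' models are evaluated, never refit. For every model pair the paired
#' difference distribution (delta R-squared) is summarized with a 95%
#' percentile interval (2.5th / 97.5th percentiles) and flagged significant
#' when that interval excludes zero.
#'
#' Resamples whose outcome is constant (zero SST) yield no R-squared; such
#' draws are recorded as missing, excluded from the summaries, and counted in
#' `n_degenerate`.
#'
#' @param fits Named list of `polyenv_fit` objects sharing the same hold-out
#'   rows.
#' @param B Number of bootstrap resamples (default 1000, must be >= 2).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return Object of class `polyenv_comparison`: tibbles `r2` (per-model
#'   median and CI) and `delta` (per-pair median, CI, `significant`), the raw
#'   draw matrices, and `n_degenerate`.
#' @export
bootstrap_r2 <- function(fits, B = 1000, seed = 1, level = 0.95) {
  B <- check_count(B, "B", min = 2L)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$model, "")
  }
  preds <- lapply(fits, function(f) f$holdout_pred)
  y <- fits[[1]]$y_holdout
  n <- length(y)
  for (f in fits) {
    if (length(f$y_holdout) != n || max(abs(f$y_holdout - y)) > 1e-12) {
      abort_polyenv("all fits must share the same hold-out rows.",
                    class = "polyenv_input_error")
    }
  }
  set.seed(seed)
  r2_draws <- matrix(NA_real_, B, length(fits),
                     dimnames = list(NULL, names(fits)))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y[idx]
    sst <- sum((yb - mean(yb))^2)
    if (sst < 1e-12) next  # degenerate resample: recorded as missing
    for (m in seq_along(fits)) {
      sse <- sum((yb - preds[[m]][idx])^2)
      r2_draws[b, m] <- 1 - sse / sst
    }
  }
  ok <- !is.na(r2_draws[, 1])
  r2 <- purrr::map_dfr(names(fits), function(m) {
    ci <- percentile_ci(r2_draws[ok, m], level)
    tibble::tibble(model = m, r2 = fits[[m]]$holdout$r2,
                   median = median(r2_draws[ok, m]),
                   lower = ci[1], upper = ci[2])
  })
  pairs <- if (length(fits) < 2L) list() else
    utils::combn(names(fits), 2L, simplify = FALSE)
  delta_draws <- lapply(pairs, function(p) {
    r2_draws[, p[1]] - r2_draws[, p[2]]
  })
  names(delta_draws) <- vapply(pairs, paste, "", collapse = " - ")
  if (length(pairs) == 0L) {
    delta <- tibble::tibble(model_1 = character(), model_2 = character(),
                            median = numeric(), lower = numeric(),
                            upper = numeric(), significant = logical())
    return(structure(list(r2 = r2, delta = delta, r2_draws = r2_draws,
                          delta_draws = delta_draws,
                          n_degenerate = sum(!ok), B = B, level = level),
                     class = "polyenv_comparison"))
  }
  delta <- purrr::map_dfr(seq_along(pairs), function(i) {
    d <- delta_draws[[i]][ok]
    ci <- percentile_ci(d, level)
    tibble::tibble(model_1 = pairs[[i]][1], model_2 = pairs[[i]][2],
                   median = median(d), lower = ci[1], upper = ci[2],
                   significant = significance_flag(d, level))
  })
  structure(list(r2 = r2, delta = delta, r2_draws = r2_draws,
                 delta_draws = delta_draws, n_degenerate = sum(!ok),
                 B = B, level = level),
            class = "polyenv_comparison")
}

#' Does a bootstrap difference distribution exclude zero?
#'
#' Applies the percentile-interval significance rule: `TRUE` iff the central
#' `level` interval (by default the 2.5th and 97.5th percentiles) of the
#' difference distribution does not contain zero.
#'
#' @param delta Numeric vector of bootstrap differences (non-empty).
#' @param level Confidence level (default 0.95).
#' @return Logical scalar.
#' @export
significance_flag <- function(delta, level = 0.95) {
  delta <- delta[!is.na(delta)]
  if (length(delta) == 0L) {
    abort_polyenv("empty difference distribution.", class = "polyenv_input_error")
  }
  ci <- percentile_ci(delta, level)
  ci[1] > 0 || ci[2] < 0
}

#' @export
print.polyenv_comparison <- function(x, ...) {
  cat(sprintf("<polyenv_comparison: %d models, B = %d (%d degenerate draws excluded)>\n",
              nrow(x$r2), x$B, x$n_degenerate))
  print(x$r2)
  print(x$delta)
  invisible(x)
}
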