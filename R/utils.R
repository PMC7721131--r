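# Internal helpers shared across modules.

abort_polyenv <- function(msg, class = "polyenv_error") {
  rlang::abort(msg, class = class)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_polyenv(sprintf("`%s` must be a single finite number.", name),
                  class = "polyenv_config_error")
  }
  if (x < lower || x > upper) {
    abort_polyenv(sprintf("`%s` must be in [%s, %s], got %s.", name,
                          format(lower), format(upper), format(x)),
                  class = "polyenv_config_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    abort_polyenv(sprintf("`%s` must be an integer >= %d.", name, min),
                  class = "polyenv_config_error")
  }
  invisible(as.integer(x))
}

#' Soft-thresholding operator
#'
#' `soft_threshold(z, t)` returns `sign(z) * max(|z| - t, 0)`, the proximal
#' operator of the L1 penalty. Exposed because several closed-form results in
#' the package's test oracles are stated in terms of it.
#'
#' @param z Numeric vector.
#' @param t Non-negative threshold.
#' @return Numeric vector of the same length as `z`.
#' @export
soft_threshold <- function(z, t) {
  sign(z) * pmax(abs(z) - t, 0)
}

# Stage-specific child seeds derived from one master seed by fixed offsets,
# so each generator stage draws from its own reproducible stream.
child_seed <- function(seed, stage) {
  offsets <- c(
    covariates = 101L, latent = 211L, gps = 307L, env = 401L,
    outcome = 503L, split = 601L, snp = 701L, discovery = 811L,
    phenotype = 907L
  )
  if (!stage %in% names(offsets)) {
    abort_polyenv(sprintf("unknown seed stage '%s'", stage))
  }
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

# Column standardization: center and scale to unit SD (denominator n - 1).
standardize_cols <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  x <- sweep(x, 2L, center, "-")
  if (is.null(scale)) scale <- apply(x, 2L, stats::sd)
  if (any(scale < 1e-12)) {
    bad <- colnames(x)[scale < 1e-12]
    abort_polyenv(sprintf("zero-variance column(s): %s",
                          paste(bad, collapse = ", ")),
                  class = "polyenv_zero_variance_error")
  }
  structure(sweep(x, 2L, scale, "/"), center = center, scale = scale)
}

# Percentile interval helper (type-7 quantiles, 2.5th/97.5th percentiles).
percentile_ci <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  stats::quantile(x, probs = c(a, 1 - a), names = FALSE, na.rm = TRUE)
}
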