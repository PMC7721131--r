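#' Socioeconomic-status composite
#'
#' Builds the SES composite as the mean of five standardized parental
#' measures (qualifications and employment of each parent, maternal age at
#' first birth): each column is z-standardized on the full sample, then
#' averaged row-wise.
#'
#' @param data Data frame containing the five measures.
#' @param cols Character vector of the five column names.
#' @return Numeric vector of composite scores, one per row.
#' @export
build_ses_composite <- function(data, cols) {
  if (length(cols) != 5L) {
    abort_polyenv("the SES composite requires exactly five measures.",
                  class = "polyenv_input_error")
  }
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort_polyenv(sprintf("missing SES column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  class = "polyenv_input_error")
  }
  x <- as.matrix(data[cols])
  if (anyNA(x)) {
    abort_polyenv("SES measures contain missing values; complete cases required.",
                  class = "polyenv_input_error")
  }
  rowMeans(scale(x))
}

#' Household chaos score
#'
#' Computes the chaos score as the mean of six rated items on a common
#' ordinal scale, after recoding the reverse-keyed items as
#' `max + min - x`.
#'
#' @param data Data frame with the items.
#' @param cols Character vector of the six item column names, in scale order.
#' @param reverse Integer positions (into `cols`) of the reverse-keyed items;
#'   defaults to items 1, 4 and 6.
#' @param scale_range Length-2 numeric giving the minimum and maximum valid
#'   item value (default the 3-point scale `c(1, 3)`).
#' @return Numeric vector of chaos scores.
#' @export
build_chaos_score <- function(data, cols, reverse = c(1L, 4L, 6L),
                              scale_range = c(1, 3)) {
  if (length(cols) != 6L) {
    abort_polyenv("the chaos score requires exactly six items.",
                  class = "polyenv_input_error")
  }
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort_polyenv(sprintf("missing chaos item(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  class = "polyenv_input_error")
  }
  x <- as.matrix(data[cols])
  if (anyNA(x) || any(x < scale_range[1]) || any(x > scale_range[2])) {
    abort_polyenv(sprintf("chaos items must lie in [%s, %s] with no missing values.",
                          scale_range[1], scale_range[2]),
                  class = "polyenv_input_error")
  }
  x[, reverse] <- sum(scale_range) - x[, reverse]
  rowMeans(x)
}

#' Filter binary life-event items by endorsement
#'
#' Applies the study's two-stage item filter: first remove the labelled
#' exclusions (outcome-relevant items), then drop any remaining item endorsed
#' by fewer than `endorsement_min` individuals.
#'
#' @param items Data frame of 0/1 item indicators.
#' @param endorsement_min Minimum endorsement count for retention
#'   (default 100; an item endorsed by exactly 100 people is retained).
#' @param excluded_labels Item names removed a priori regardless of
#'   endorsement.
#' @return A tibble with one row per input item: `item`, `endorsed`
#'   (count), `excluded` (labelled exclusion), `retained` (logical).
#' @export
filter_life_events <- function(items, endorsement_min = 100,
                               excluded_labels = character()) {
  x <- as.matrix(items)
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    abort_polyenv("life-event items must be binary 0/1 with no missing values.",
                  class = "polyenv_input_error")
  }
  endorsed <- colSums(x)
  excluded <- colnames(x) %in% excluded_labels
  tibble::tibble(
    item = colnames(x),
    endorsed = as.integer(endorsed),
    excluded = excluded,
    retained = !excluded & endorsed >= endorsement_min
  )
}

#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles through their ranks with the Blom offset:
#' `qnorm((rank - 3/8) / (n + 1/4))`. Ties receive averaged ranks, so the
#' transform is deterministic and strictly monotone in the underlying order.
#'
#' @param y Numeric vector (no missing values).
#' @return Transformed numeric vector.
#' @export
rank_inverse_normal <- function(y) {
  if (anyNA(y)) {
    abort_polyenv("missing values are not supported.", class = "polyenv_input_error")
  }
  if (length(unique(y)) < 2L) {
    abort_polyenv("the transform is undefined for a constant vector.",
                  class = "polyenv_input_error")
  }
  r <- rank(y, ties.method = "average")
  qnorm((r - 3 / 8) / (length(y) + 1 / 4))
}

#' Residualize columns on covariates
#'
#' Replaces each column of `x` by the standardized residual from its
#' least-squares regression on the covariates (plus intercept): the workhorse
#' behind the convention of regressing all study variables on age, sex,
#' genetic principal components and genotyping chip before analysis.
#'
#' @param x Matrix or data frame of columns to residualize.
#' @param covariates Matrix or data frame of covariates (full rank).
#' @return Matrix of residualized, standardized columns (mean 0, SD 1,
#'   exactly uncorrelated with every covariate).
#' @export
residualize <- function(x, covariates) {
  x <- as.matrix(x)
  z <- cbind(1, as.matrix(covariates))
  if (anyNA(x) || anyNA(z)) {
    abort_polyenv("missing values are not supported.", class = "polyenv_input_error")
  }
  qz <- qr(z)
  if (qz$rank < ncol(z)) {
    abort_polyenv("covariate matrix is rank deficient.",
                  class = "polyenv_input_error")
  }
  res <- qr.resid(qz, x)
  sds <- apply(res, 2L, stats::sd)
  if (any(sds < 1e-10)) {
    bad <- colnames(x)[sds < 1e-10]
    abort_polyenv(sprintf(
      "column(s) collinear with covariates leave zero residual variance: %s",
      paste(bad, collapse = ", ")), class = "polyenv_zero_variance_error")
  }
  scale(res)[, , drop = FALSE]
}

#' Random train / hold-out split
#'
#' Randomly partitions `n` rows into a training fraction and a hold-out
#' remainder (default 80/20), reproducibly by seed.
#'
#' @param n Number of rows (>= 10).
#' @param fraction Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return Character vector of length `n` with values "train" / "holdout".
#' @export
split_sample <- function(n, fraction = 0.8, seed = 1) {
  n <- check_count(n, "n", min = 10L)
  check_scalar_number(fraction, "fraction", 0.1, 0.95)
  set.seed(child_seed(seed, "split"))
  n_train <- round(fraction * n)
  flags <- rep("holdout", n)
  flags[sample.int(n, n_train)] <- "train"
  flags
}

#' Build an analysis-ready predictor panel
#'
#' Runs the full preprocessing chain on a score-tier cohort (or any table
#' with role labels): rank-based inverse normal transformation of the
#' outcome, residualization of the outcome and every non-covariate predictor
#' on the covariates, an 80/20 train / hold-out split, and standardization of
#' all analysis columns using training-set moments only (applied unchanged to
#' the hold-out rows, so no information leaks from the evaluation set).
#'
#' @param data Data frame containing outcome, predictors and covariates.
#' @param roles Tibble with columns `column`, `role` (one of `outcome`,
#'   `gps`, `environment`, `covariate`).
#' @param fraction Training fraction for [split_sample()].
#' @param seed Seed for the split.
#' @param transform_outcome Apply [rank_inverse_normal()] to the outcome
#'   before residualization (default TRUE).
#' @return An object of class `polyenv_panel`: list with `x` (matrix of
#'   residualized standardized predictors), `y` (processed outcome), `roles`,
#'   `split` (train/holdout flags), and `covariates`.
#' @export
prepare_panel <- function(data, roles, fraction = 0.8, seed = 1,
                          transform_outcome = TRUE) {
  stopifnot(all(c("column", "role") %in% names(roles)))
  outcome_col <- roles$column[roles$role == "outcome"]
  cov_cols <- roles$column[roles$role == "covariate"]
  pred_cols <- roles$column[roles$role %in% c("gps", "environment")]
  if (length(outcome_col) != 1L) {
    abort_polyenv("roles must name exactly one outcome column.",
                  class = "polyenv_input_error")
  }
  y_raw <- data[[outcome_col]]
  if (transform_outcome) y_raw <- rank_inverse_normal(y_raw)
  covariates <- as.matrix(data[cov_cols])
  resid_all <- residualize(cbind(.outcome = y_raw, as.matrix(data[pred_cols])),
                           covariates)
  split <- split_sample(nrow(data), fraction = fraction, seed = seed)
  train <- split == "train"
  x <- resid_all[, -1L, drop = FALSE]
  y <- resid_all[, 1L]
  centers <- colMeans(x[train, , drop = FALSE])
  scales <- apply(x[train, , drop = FALSE], 2L, stats::sd)
  x <- sweep(sweep(x, 2L, centers, "-"), 2L, scales, "/")
  y <- (y - mean(y[train])) / stats::sd(y[train])
  colnames(x) <- pred_cols
  structure(list(
    x = x, y = y,
    roles = roles[roles$column %in% pred_cols, , drop = FALSE],
    split = split, covariates = covariates
  ), class = "polyenv_panel")
}

#' @export
print.polyenv_panel <- function(x, ...) {
  cat(sprintf("<polyenv_panel: %d x %d predictors (%d gps, %d environment); %d train / %d holdout>\n",
              nrow(x$x), ncol(x$x),
              sum(x$roles$role == "gps"), sum(x$roles$role == "environment"),
              sum(x$split == "train"), sum(x$split == "holdout")))
  invisible(x)
}

panel_rows <- function(panel, which = c("train", "holdout"), roles = NULL) {
  which <- match.arg(which)
  keep_rows <- panel$split == which
  keep_cols <- if (is.null(roles)) rep(TRUE, ncol(panel$x)) else
    panel$roles$role %in% roles
  list(x = panel$x[keep_rows, keep_cols, drop = FALSE], y = panel$y[keep_rows])
}
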