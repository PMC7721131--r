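# broom-style tidiers for the package's fitted objects.

#' @rdname polyenv_tidiers
#' @name polyenv_tidiers
#' @title Tidy and summarize fitted polyenv objects
#' @description `tidy()` returns one row per estimated quantity; `glance()`
#'   returns a one-row model summary. Methods exist for penalized fits,
#'   bootstrap comparisons, mediation results, interaction selections and
#'   summary-statistic polygenic score solutions.
#' @param x A fitted polyenv object.
#' @param ... Unused.
NULL

#' @rdname polyenv_tidiers
#' @export
tidy.polyenv_fit <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta),
                 active = x$beta != 0)
}

#' @rdname polyenv_tidiers
#' @export
glance.polyenv_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(model = x$model, alpha = x$alpha, lambda = x$lambda,
                   n_active = length(x$active)),
    x$holdout
  )
}

#' @rdname polyenv_tidiers
#' @export
tidy.polyenv_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(x$r2, estimate = "r2"),
                  quantity = "r2", .before = 1),
    dplyr::mutate(x$delta, quantity = "delta_r2",
                  model = paste(.data$model_1, "-", .data$model_2),
                  estimate = NA_real_, .before = 1)[
                    c("quantity", "model", "estimate", "median", "lower",
                      "upper", "significant")]
  )
}

#' @rdname polyenv_tidiers
#' @export
glance.polyenv_comparison <- function(x, ...) {
  tibble::tibble(n_models = nrow(x$r2), B = x$B, level = x$level,
                 n_degenerate = x$n_degenerate)
}

#' @rdname polyenv_tidiers
#' @export
tidy.polyenv_mediation <- function(x, ...) {
  dplyr::mutate(x$estimates, orientation = x$orientation)
}

#' @rdname polyenv_tidiers
#' @export
glance.polyenv_mediation <- function(x, ...) {
  est <- setNames(x$estimates$estimate, x$estimates$term)
  tibble::tibble(orientation = x$orientation,
                 indirect = unname(est["indirect"]),
                 proportion_mediated = unname(est["proportion_mediated"]),
                 B = x$B)
}

#' @rdname polyenv_tidiers
#' @export
tidy.polyenv_selection <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(type = "main", term = x$mains$term,
                   estimate = x$mains$coefficient,
                   selected = x$mains$selected, class = NA_character_),
    tibble::tibble(type = "pair",
                   term = paste0(x$pairs$var1, ":", x$pairs$var2),
                   estimate = x$pairs$weight, selected = TRUE,
                   class = x$pairs$class)
  )
}

#' @rdname polyenv_tidiers
#' @export
glance.polyenv_selection <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$candidates),
    n_selected_mains = sum(x$mains$selected),
    n_selected_pairs = nrow(x$pairs),
    n_gxe = sum(x$pairs$class == "GxE"),
    lambda = x$lambda
  )
}

#' @rdname polyenv_tidiers
#' @export
tidy.polyenv_lassosum <- function(x, ...) {
  tibble::tibble(snp = names(x$beta), estimate = unname(x$beta),
                 active = x$beta != 0)
}

#' @rdname polyenv_tidiers
#' @export
glance.polyenv_lassosum <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, s = x$s, n_snps = length(x$beta),
                 n_active = sum(x$beta != 0), objective = x$objective)
}
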