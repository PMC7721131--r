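#' LD reference panel
#'
#' Wraps a reference genotype matrix together with LD-block boundaries. The
#' blocks must be ordered, non-overlapping and cover every SNP column
#' exactly once; within each block the reference columns are standardized so
#' that their cross-product is a correlation matrix.
#'
#' @param genotypes n x m allele-count matrix with SNP ids as column names.
#' @param blocks Tibble/data frame with columns `start`, `end` (1-based,
#'   inclusive SNP-index intervals).
#' @return An object of class `polyenv_ld`.
#' @export
ld_reference <- function(genotypes, blocks) {
  genotypes <- as.matrix(genotypes)
  m <- ncol(genotypes)
  blocks <- tibble::as_tibble(blocks)
  stopifnot(all(c("start", "end") %in% names(blocks)))
  idx <- unlist(Map(seq, blocks$start, blocks$end))
  if (length(idx) != m || any(sort(idx) != seq_len(m)) || anyDuplicated(idx)) {
    abort_polyenv("blocks must partition the SNP index 1..m with no overlap.",
                  class = "polyenv_input_error")
  }
  structure(list(genotypes = genotypes, blocks = blocks,
                 snp_ids = colnames(genotypes)),
            class = "polyenv_ld")
}

validate_summary_stats <- function(stats) {
  stats <- tibble::as_tibble(stats)
  needed <- c("snp", "r")
  if (!all(needed %in% names(stats))) {
    abort_polyenv("summary statistics need at least columns `snp` and `r`.",
                  class = "polyenv_input_error")
  }
  if (anyDuplicated(stats$snp)) {
    abort_polyenv("summary-statistic SNP ids must be unique.",
                  class = "polyenv_input_error")
  }
  if (any(abs(stats$r) > 1)) {
    abort_polyenv("per-SNP correlations must satisfy |r| <= 1.",
                  class = "polyenv_input_error")
  }
  stats
}

AMBIGUOUS_PAIRS <- c("A/T", "T/A", "C/G", "G/C")

#' Align summary statistics to reference-panel alleles
#'
#' Applies the standard allele-alignment convention: when the effect and
#' other alleles are swapped between the summary statistics and the
#' reference, the correlation sign is flipped; strand-ambiguous SNPs (A/T,
#' C/G) and SNPs whose allele pairs cannot be reconciled are dropped.
#'
#' @param stats Summary statistics tibble with columns `snp`, `a1`, `a2`,
#'   `r` (and optionally `n`).
#' @param reference_alleles Tibble with columns `snp`, `a1`, `a2` giving the
#'   reference panel's counted/other alleles.
#' @return The aligned statistics tibble (rows dropped as needed), with
#'   attributes `n_flipped` and `dropped` (character vector of SNP ids).
#' @export
align_summary_stats <- function(stats, reference_alleles) {
  stats <- validate_summary_stats(stats)
  ref <- tibble::as_tibble(reference_alleles)
  merged <- dplyr::inner_join(stats, ref, by = "snp", suffix = c("", "_ref"))
  pair <- paste(merged$a1, merged$a2, sep = "/")
  ambiguous <- pair %in% AMBIGUOUS_PAIRS
  same <- merged$a1 == merged$a1_ref & merged$a2 == merged$a2_ref
  flipped <- merged$a1 == merged$a2_ref & merged$a2 == merged$a1_ref
  keep <- !ambiguous & (same | flipped)
  out <- merged[keep, , drop = FALSE]
  out$r <- ifelse(flipped[keep], -out$r, out$r)
  dropped <- c(setdiff(stats$snp, merged$snp), merged$snp[!keep])
  out <- out[names(stats)]
  attr(out, "n_flipped") <- sum(flipped & keep)
  attr(out, "dropped") <- dropped
  out
}

#' Summary-statistic penalized regression (lassosum)
#'
#' Solves the summary-statistic analogue of the lasso: minimize (up to the
#' constant `y'y`)
#' \deqn{(1-s)\,\beta' R \beta - 2\beta' r + s\,\beta'\beta + 2\lambda \lVert\beta\rVert_1}
#' where `r` holds the per-SNP phenotype-genotype correlations and `R` is the
#' block-diagonal LD correlation matrix from the reference panel. The problem
#' separates over LD blocks and is solved blockwise by coordinate descent;
#' `s = 1` removes the LD term entirely (each coefficient is then the
#' soft-threshold of its `r`), and at `lambda = 0, s = 1` the solution equals
#' `r` elementwise.
#'
#' @param stats Summary statistics (columns `snp`, `r`; ids must match the
#'   reference columns in order — use [align_summary_stats()] first when
#'   alleles may disagree).
#' @param ld An [ld_reference()].
#' @param lambda Non-negative L1 penalty.
#' @param s Mixing parameter in \[0, 1\] (L2/identity share of the LD term).
#' @param tol Convergence tolerance on the maximum coefficient change
#'   (default 1e-7).
#' @param max_sweeps Maximum coordinate-descent sweeps per block.
#' @return Object of class `polyenv_lassosum`: named coefficient vector
#'   `beta`, the tuning values, and the objective value (without the `y'y`
#'   constant).
#' @export
lassosum_fit <- function(stats, ld, lambda, s, tol = 1e-7, max_sweeps = 10000L) {
  stats <- validate_summary_stats(stats)
  stopifnot(inherits(ld, "polyenv_ld"))
  check_scalar_number(lambda, "lambda", 0)
  check_scalar_number(s, "s", 0, 1)
  if (!identical(stats$snp, ld$snp_ids)) {
    abort_polyenv("summary-statistic SNPs must match the reference panel columns in order.",
                  class = "polyenv_alignment_error")
  }
  m <- length(stats$r)
  beta <- numeric(m)
  for (b in seq_len(nrow(ld$blocks))) {
    idx <- ld$blocks$start[b]:ld$blocks$end[b]
    R <- block_correlation(ld$genotypes[, idx, drop = FALSE])
    sol <- cd_lassosum_block(R, stats$r[idx], lambda, s, numeric(length(idx)),
                             tol, as.integer(max_sweeps))
    beta[idx] <- sol$beta
  }
  names(beta) <- stats$snp
  structure(list(beta = beta, lambda = lambda, s = s,
                 objective = lassosum_objective(stats$r, ld, beta, lambda, s)),
            class = "polyenv_lassosum")
}

block_correlation <- function(g) {
  R <- suppressWarnings(cor(g))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  R
}

#' Lassosum objective value
#'
#' Evaluates `(1-s) b'Rb - 2 b'r + s b'b + 2 lambda ||b||_1` with the
#' block-diagonal reference LD matrix (the `y'y` constant of the full loss is
#' omitted as it does not depend on `b`). Exposed for oracle tests.
#'
#' @param r Per-SNP correlation vector.
#' @param ld An [ld_reference()].
#' @param beta Coefficient vector.
#' @param lambda,s Tuning parameters.
#' @return Scalar objective value.
#' @export
lassosum_objective <- function(r, ld, beta, lambda, s) {
  quad <- 0
  for (b in seq_len(nrow(ld$blocks))) {
    idx <- ld$blocks$start[b]:ld$blocks$end[b]
    R <- block_correlation(ld$genotypes[, idx, drop = FALSE])
    quad <- quad + as.numeric(t(beta[idx]) %*% R %*% beta[idx])
  }
  (1 - s) * quad - 2 * sum(beta * r) + s * sum(beta^2) +
    2 * lambda * sum(abs(beta))
}

#' Polygenic scores for individuals
#'
#' Scores each individual as the allele-count-weighted sum of per-SNP
#' coefficients: `score_i = sum_j genotype_ij * beta_j`.
#'
#' @param genotypes n x m allele-count matrix, columns aligned (by name) to
#'   the solution's SNPs.
#' @param solution A `polyenv_lassosum` fit, or a named coefficient vector.
#' @return Numeric vector of length n.
#' @export
score_individuals <- function(genotypes, solution) {
  beta <- if (inherits(solution, "polyenv_lassosum")) solution$beta else solution
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != length(beta)) {
    abort_polyenv("genotype columns do not match the coefficient vector.",
                  class = "polyenv_input_error")
  }
  if (!is.null(colnames(genotypes)) && !is.null(names(beta))) {
    if (!setequal(colnames(genotypes), names(beta))) {
      abort_polyenv("genotype SNP names do not match the solution SNPs.",
                    class = "polyenv_input_error")
    }
    genotypes <- genotypes[, names(beta), drop = FALSE]
  }
  as.numeric(genotypes %*% beta)
}

#' Tune (lambda, s) for a polygenic score against a training phenotype
#'
#' Fits the summary-statistic model at every grid point, scores the tuning
#' individuals, and returns the pair maximizing squared correlation with the
#' tuning phenotype. Grid points yielding constant (e.g. all-zero) scores get
#' R-squared 0 rather than an error.
#'
#' @param stats,ld As in [lassosum_fit()].
#' @param lambda_grid,s_grid Non-empty numeric grids.
#' @param tuning_genotypes Allele-count matrix for the tuning sample.
#' @param tuning_phenotype Numeric phenotype for the tuning sample.
#' @return List with `lambda`, `s`, `solution` (the refit at the best pair),
#'   and `grid` (tibble of `lambda`, `s`, `r2` for every point).
#' @export
tune_gps <- function(stats, ld, lambda_grid, s_grid,
                     tuning_genotypes, tuning_phenotype) {
  if (length(lambda_grid) < 1 || length(s_grid) < 1) {
    abort_polyenv("tuning grids must be non-empty.",
                  class = "polyenv_config_error")
  }
  grid <- tidyr::expand_grid(lambda = sort(lambda_grid, decreasing = TRUE),
                             s = sort(s_grid))
  grid$r2 <- purrr::pmap_dbl(grid, function(lambda, s) {
    sol <- lassosum_fit(stats, ld, lambda, s)
    sc <- score_individuals(tuning_genotypes, sol)
    if (stats::sd(sc) < 1e-12) return(0)
    cor(sc, tuning_phenotype)^2
  })
  best <- grid[which.max(grid$r2), ]
  list(lambda = best$lambda, s = best$s,
       solution = lassosum_fit(stats, ld, best$lambda, best$s),
       grid = grid)
}

#' @export
print.polyenv_lassosum <- function(x, ...) {
  cat(sprintf("<polyenv_lassosum: %d SNPs, %d nonzero; lambda = %.4g, s = %.2f>\n",
              length(x$beta), sum(x$beta != 0), x$lambda, x$s))
  invisible(x)
}
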