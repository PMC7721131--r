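roles_for <- function(p_gps, p_env) {
  tibble::tibble(
    column = c(paste0("g", seq_len(p_gps), recycle0 = TRUE),
               paste0("e", seq_len(p_env), recycle0 = TRUE)),
    role = c(rep("gps", p_gps), rep("environment", p_env)))
}

test_that("candidate enumeration counts p(p-1)/2 and classifies pairs", {
  expect_equal(nrow(build_candidates(roles_for(1, 1))), 1L)
  expect_equal(nrow(build_candidates(roles_for(3, 2))), 10L)
  expect_equal(nrow(build_candidates(roles_for(20, 13))), 528L)
  cand <- build_candidates(roles_for(2, 2))
  expect_equal(sum(cand$class == "GxE"), 4L)
  expect_equal(sum(cand$class == "GxG"), 1L)
  expect_equal(sum(cand$class == "ExE"), 1L)
  expect_false(any(cand$var1 == cand$var2))
  expect_equal(anyDuplicated(paste(cand$var1, cand$var2)), 0L)
  expect_error(build_candidates(roles_for(1, 0)), class = "polyenv_input_error")
})

test_that("lambda at or beyond lambda_max yields an empty model", {
  set.seed(1)
  x <- scale(matrix(rnorm(300 * 4), 300)); colnames(x) <- paste0("v", 1:4)
  y <- as.numeric(x %*% c(1, 0.5, 0, 0)) + rnorm(300)
  sel <- fit_hierarchical(x, y, n_lambda = 1, cv_folds = 3, seed = 1)
  # the single-lambda path sits at lambda_max: full shrinkage
  expect_equal(nrow(sel$pairs), 0L)
  expect_equal(sum(sel$mains$selected), 0L)
})

test_that("every hierarchical selection satisfies strong hierarchy", {
  for (s in 1:20) {
    set.seed(s)
    n <- 150; p <- 4
    x <- scale(matrix(rnorm(n * p), n)); colnames(x) <- paste0("v", 1:p)
    beta <- rnorm(p) * rbinom(p, 1, 0.6)
    y <- as.numeric(x %*% beta) +
      0.8 * rbinom(1, 1, 0.5) * x[, 1] * x[, 2] + rnorm(n)
    sel <- fit_hierarchical(x, y, n_lambda = 8, cv_folds = 3, seed = s)
    if (nrow(sel$pairs) > 0) {
      mains <- sel$mains$term[sel$mains$selected]
      expect_true(all(sel$pairs$var1 %in% mains))
      expect_true(all(sel$pairs$var2 %in% mains))
    }
  }
})

test_that("the proximal solver is monotone and optimal on tiny problems", {
  set.seed(2)
  n <- 80; p <- 3
  x <- scale(matrix(rnorm(n * p), n)); colnames(x) <- paste0("v", 1:p)
  y <- as.numeric(x %*% c(1, -0.5, 0)) + 0.7 * x[, 1] * x[, 2] + rnorm(n)
  sel <- fit_hierarchical(x, y, n_lambda = 6, cv_folds = 3, seed = 2,
                          tol = 1e-8, maxit = 50000)
  expect_true(all(diff(sel$objective_trace) <= 1e-12))

  # KKT certificate of global optimality for the convex objective
  cand <- sel$candidates
  design <- polyenv:::interaction_design(x, cand)
  yc <- y - mean(y)
  nfull <- nrow(x)
  grad <- as.numeric(crossprod(design$z, design$z %*% sel$theta - yc)) / nfull
  lam <- sel$lambda; w <- sel$pair_weight
  bmain <- sel$theta[1:p]
  for (j in 1:p) {
    if (abs(bmain[j]) > 1e-8) {
      expect_lt(abs(grad[j] + lam * sign(bmain[j])), 1e-6)
    } else {
      expect_lte(abs(grad[j]), lam + 1e-6)
    }
  }
  a <- matrix(sel$theta[-(1:p)], nrow = 3)
  ga <- matrix(grad[-(1:p)], nrow = 3)
  for (g in seq_len(ncol(a))) {
    nrm <- sqrt(sum(a[, g]^2))
    if (nrm > 1e-8) {
      expect_lt(max(abs(ga[, g] + lam * w * a[, g] / nrm)), 1e-6)
    } else {
      expect_lte(sqrt(sum(ga[, g]^2)), lam * w + 1e-6)
    }
  }

  # a generic numerical minimizer cannot do better
  obj <- function(theta) hierarchical_objective(design, yc, theta, lam, w)
  best <- obj(sel$theta)
  set.seed(3)
  for (k in 1:4) {
    start <- sel$theta + rnorm(length(sel$theta), sd = 0.2)
    nm <- optim(start, obj, method = "Nelder-Mead",
                control = list(maxit = 20000, reltol = 1e-14))
    expect_lte(best, nm$value + 1e-5)
  }
})

test_that("planted interactions are recovered with both mains active", {
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    x <- scale(matrix(rnorm(2000 * 6), 2000)); colnames(x) <- paste0("v", 1:6)
    y <- x[, 1] + x[, 2] + 1.5 * x[, 1] * x[, 2] + rnorm(2000)
    sel <- fit_hierarchical(x, y, cv_folds = 5, seed = s)
    found <- any((sel$pairs$var1 == "v1" & sel$pairs$var2 == "v2"))
    mains <- sel$mains$term[sel$mains$selected]
    hits <- hits + (found && all(c("v1", "v2") %in% mains))
  }
  expect_gte(hits, 4)
})

test_that("additive-only data yields no interactions in most seeds", {
  zeros <- 0
  for (s in 1:6) {
    set.seed(s)
    x <- scale(matrix(rnorm(2000 * 6), 2000)); colnames(x) <- paste0("v", 1:6)
    y <- as.numeric(x %*% c(1, 0.5, 0.3, 0, 0, 0)) + rnorm(2000)
    sel <- fit_hierarchical(x, y, cv_folds = 5, seed = s)
    zeros <- zeros + (nrow(sel$pairs) == 0)
  }
  expect_gte(zeros, 5)
})

test_that("non-finite inputs are rejected", {
  x <- matrix(c(1, NA, 2, 3), 2)
  expect_error(fit_hierarchical(x, c(1, 2)), class = "polyenv_input_error")
})

test_that("GxE refit augments the design and degenerates to G+E when empty", {
  coh <- simulate_score_cohort(generator_config(
    n_individuals = 2500, seed = 33,
    gxe_effects = data.frame(gps = 1, env = 1, coef = 0.35)))
  panel <- prepare_panel(coh$data, coh$roles, seed = 33)
  cfg <- tiny_enet_config(seed = 33)
  base <- fit_enet_model(panel, "G+E", cfg)
  same <- refit_with_gxe(panel, tibble::tibble(var1 = character(),
                                               var2 = character()), cfg)
  expect_equal(same$beta, base$beta)
  expect_equal(same$holdout$r2, base$holdout$r2)
  aug <- refit_with_gxe(panel,
                        tibble::tibble(var1 = "gps_01", var2 = "ses",
                                       class = "GxE"), cfg)
  expect_equal(aug$model, "G*E")
  expect_true("gps_01:ses" %in% names(aug$beta))
  expect_gt(aug$holdout$r2, base$holdout$r2)
  cmp <- bootstrap_r2(list(`G+E` = base, `G*E` = aug), B = 300, seed = 33)
  d <- cmp$delta[cmp$delta$model_1 == "G+E", ]
  expect_true(d$significant)
  expect_lt(d$upper, 0)  # G+E minus G*E is negative: the GxE term helps
  expect_error(refit_with_gxe(panel,
                              tibble::tibble(var1 = "nope", var2 = "ses")),
               class = "polyenv_input_error")
  expect_error(refit_with_gxe(panel,
                              tibble::tibble(var1 = "gps_01", var2 = "gps_02",
                                             class = "GxG")),
               class = "polyenv_input_error")
})

test_that("null GxE refits do not improve hold-out prediction", {
  contains_zero <- 0
  for (s in 1:3) {
    coh <- simulate_score_cohort(generator_config(n_individuals = 2000,
                                                  seed = 100 + s))
    panel <- prepare_panel(coh$data, coh$roles, seed = s)
    cfg <- tiny_enet_config(seed = s)
    base <- fit_enet_model(panel, "G+E", cfg)
    aug <- refit_with_gxe(panel,
                          tibble::tibble(var1 = "gps_02", var2 = "chaos",
                                         class = "GxE"), cfg)
    cmp <- bootstrap_r2(list(a = base, b = aug), B = 300, seed = s)
    contains_zero <- contains_zero + (!cmp$delta$significant)
  }
  expect_gte(contains_zero, 2)
})
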