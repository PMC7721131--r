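#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of the two-tier generator: a SNP-level
#' mini-cohort (for testing summary-statistic polygenic scoring) and a
#' score-level cohort of polygenic scores (GPS), environmental measures,
#' covariates and a continuous outcome with controllable gene-environment
#' correlation (rGE), mediation structure, GxE product effects and
#' model-level R-squared targets.
#'
#' The score-level outcome model uses three latent variables: a genetic
#' composite `G`, an environmental latent `E1` correlated with `G`, and an
#' environmental latent `E2` orthogonal to `G`. Splitting the environmental
#' signal in two gives the generator enough freedom to hit the G-only,
#' E-only and joint G+E population R-squared targets *and* the rGE target
#' exactly (see the methods vignette for the closed-form solve).
#'
#' @param n_individuals Cohort size (default 7026).
#' @param n_snps,n_ld_blocks,maf_range,ld_rho SNP-tier settings: number of
#'   SNPs (must divide evenly into `n_ld_blocks` blocks), minor-allele
#'   frequency range in (0, 0.5], and the within-block autoregressive
#'   haplotype correlation driving LD.
#' @param n_discovery Discovery-sample size for the independent replicate on
#'   which GWAS-style summary statistics are computed.
#' @param snp_h2 Variance of the SNP-tier phenotype explained by causal SNPs.
#' @param causal_per_block Number of causal SNPs per LD block (0 for a null
#'   model).
#' @param n_gps,n_env_continuous,n_env_binary Score-tier panel dimensions
#'   (defaults 20, 2, 11, emulating 20 GPS plus an SES composite, a household
#'   chaos score, and 11 binary life events).
#' @param rge Target correlation in \[-1, 1\] between the latent genetic
#'   composite and the population environmental prediction composite.
#' @param prop_g_mediated,prop_e_confounded Optional mediation fractions in
#'   \[0, 1\]; these drive the path coefficients only when `target_r2` is
#'   `NULL` (when R-squared targets are given they pin down the realized
#'   proportions, which are reported in the truth record).
#' @param gxe_effects Optional data frame / tibble with columns `gps`, `env`
#'   (1-based indices into the GPS and environment panels) and `coef`
#'   (standardized product-term coefficient).
#' @param target_r2 Named numeric vector with entries `G`, `E` and optionally
#'   `GE`: intended population R-squared of the G-only, E-only and joint
#'   models on the latent scale. If `GE` is omitted it is implied by
#'   (`G`, `E`, `rge`) under a single environmental latent.
#' @param total_r2 Joint R-squared used only when `target_r2` is `NULL` and
#'   the mediation-fraction parameterization is active.
#' @param gps_loading,env_loading,binary_loading Indicator loadings of the
#'   observed GPS, continuous environments and binary life-event latents on
#'   their composite (reliability-like constants in (0, 1)).
#' @param endorsement_range Range of binary life-event endorsement rates.
#' @param covariate_effect Scale of the covariate contributions mixed into
#'   every observed column (makes covariate residualization consequential).
#' @param seed Master seed; stage-specific child seeds are derived from it by
#'   fixed documented offsets, so identical config + seed gives bit-identical
#'   output.
#' @return An object of class `polyenv_config` (a validated list).
#' @export
generator_config <- function(n_individuals = 7026,
                             n_snps = 120,
                             n_ld_blocks = 6,
                             maf_range = c(0.05, 0.5),
                             ld_rho = 0.7,
                             n_discovery = 10000,
                             snp_h2 = 0.3,
                             causal_per_block = 1,
                             n_gps = 20,
                             n_env_continuous = 2,
                             n_env_binary = 11,
                             rge = 0.38,
                             prop_g_mediated = NULL,
                             prop_e_confounded = NULL,
                             gxe_effects = NULL,
                             target_r2 = c(G = 0.18, E = 0.30, GE = 0.36),
                             total_r2 = 0.36,
                             gps_loading = 0.6,
                             env_loading = 0.8,
                             binary_loading = 0.6,
                             endorsement_range = c(0.05, 0.5),
                             covariate_effect = 0.1,
                             seed = 1) {
  n_individuals <- check_count(n_individuals, "n_individuals")
  n_snps <- check_count(n_snps, "n_snps")
  n_ld_blocks <- check_count(n_ld_blocks, "n_ld_blocks")
  n_discovery <- check_count(n_discovery, "n_discovery")
  n_gps <- check_count(n_gps, "n_gps")
  n_env_continuous <- check_count(n_env_continuous, "n_env_continuous", min = 0L)
  n_env_binary <- check_count(n_env_binary, "n_env_binary", min = 0L)
  causal_per_block <- check_count(causal_per_block, "causal_per_block", min = 0L)
  check_scalar_number(rge, "rge", -1, 1)
  check_scalar_number(snp_h2, "snp_h2", 0, 1)
  check_scalar_number(ld_rho, "ld_rho", -1, 1)
  check_scalar_number(total_r2, "total_r2", 0, 1)
  if (!is.null(prop_g_mediated)) check_scalar_number(prop_g_mediated, "prop_g_mediated", 0, 1)
  if (!is.null(prop_e_confounded)) check_scalar_number(prop_e_confounded, "prop_e_confounded", 0, 1)
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort_polyenv("`maf_range` must be an increasing pair within (0, 0.5].",
                  class = "polyenv_config_error")
  }
  if (length(endorsement_range) != 2L || any(endorsement_range <= 0) ||
      any(endorsement_range >= 1) || endorsement_range[1] > endorsement_range[2]) {
    abort_polyenv("`endorsement_range` must be an increasing pair within (0, 1).",
                  class = "polyenv_config_error")
  }
  for (nm in c("gps_loading", "env_loading", "binary_loading")) {
    check_scalar_number(get(nm), nm, 0, 1)
  }
  if (!is.null(target_r2)) {
    if (is.null(names(target_r2)) || !all(c("G", "E") %in% names(target_r2))) {
      abort_polyenv("`target_r2` must be a named vector with at least entries 'G' and 'E'.",
                    class = "polyenv_config_error")
    }
    if (any(target_r2 < 0) || any(target_r2 > 1)) {
      abort_polyenv("`target_r2` entries must lie in [0, 1].",
                    class = "polyenv_config_error")
    }
  }
  if (!is.null(gxe_effects)) {
    gxe_effects <- tibble::as_tibble(gxe_effects)
    if (!all(c("gps", "env", "coef") %in% names(gxe_effects))) {
      abort_polyenv("`gxe_effects` needs columns gps, env, coef.",
                    class = "polyenv_config_error")
    }
    if (any(gxe_effects$gps < 1) || any(gxe_effects$gps > n_gps) ||
        any(gxe_effects$env < 1) ||
        any(gxe_effects$env > n_env_continuous + n_env_binary)) {
      abort_polyenv("`gxe_effects` indices out of range for the configured panel.",
                    class = "polyenv_config_error")
    }
  }
  seed <- check_count(seed, "seed", min = 0L)
  cfg <- list(
    n_individuals = n_individuals, n_snps = n_snps, n_ld_blocks = n_ld_blocks,
    maf_range = maf_range, ld_rho = ld_rho, n_discovery = n_discovery,
    snp_h2 = snp_h2, causal_per_block = causal_per_block,
    n_gps = n_gps, n_env_continuous = n_env_continuous,
    n_env_binary = n_env_binary, rge = rge,
    prop_g_mediated = prop_g_mediated, prop_e_confounded = prop_e_confounded,
    gxe_effects = gxe_effects, target_r2 = target_r2, total_r2 = total_r2,
    gps_loading = gps_loading, env_loading = env_loading,
    binary_loading = binary_loading, endorsement_range = endorsement_range,
    covariate_effect = covariate_effect, seed = seed
  )
  class(cfg) <- "polyenv_config"
  # fail early on infeasible variance budgets
  solve_score_paths(cfg)
  cfg
}

# Closed-form solve for the latent path coefficients of the score-tier
# outcome model. Latents: G, E1 = rho*G + sqrt(1-rho^2)*z, E2 orthogonal.
# Outcome (before GxE and noise): y = w_g*G + w_1*E1 + w_2*E2. Writing
# cg = cov(y, G), c1 = cov(y, E1), c2 = cov(y, E2), the population targets are
#   R2_G  = cg^2
#   R2_E  = c1^2 + c2^2                      (E-model uses span(E1, E2))
#   rge   = rho * c1 / sqrt(R2_E)            (cor of G with the E prediction)
#   R2_GE = (cg^2 + c1^2 - 2 rho cg c1)/(1 - rho^2) + c2^2
# Given (R2_G, R2_E, R2_GE, rge) these solve in closed form; see vignette.
solve_score_paths <- function(cfg) {
  tr <- cfg$target_r2
  if (is.null(tr)) {
    return(solve_paths_from_props(cfg))
  }
  r2g <- unname(tr[["G"]]); r2e <- unname(tr[["E"]])
  rge <- cfg$rge
  cg <- sqrt(r2g); sq_s <- sqrt(r2e)
  if ("GE" %in% names(tr)) {
    r2ge <- unname(tr[["GE"]])
    if (r2ge > 1) infeasible("joint R2 target exceeds 1")
    if (r2ge < max(r2g, r2e) - 1e-12) {
      infeasible("joint R2 target is below a marginal R2 target")
    }
    t <- rge * sq_s
    if (abs(t) < 1e-12) {
      if (abs(r2ge - (r2g + r2e)) > 1e-9) {
        infeasible("with rge = 0 the joint R2 must equal R2_G + R2_E")
      }
      c1 <- 0; c2 <- sq_s; rho <- 0
    } else if (abs(r2e - r2ge) < 1e-12) {
      infeasible("joint R2 equal to R2_E is incompatible with nonzero rge")
    } else {
      num <- t^2 * (r2e - r2ge)
      den <- (cg - t)^2 + (r2e - r2ge)
      c1sq <- num / den
      if (!is.finite(c1sq) || c1sq <= 0 || den >= 0) {
        infeasible("R2 targets and rge are jointly unattainable (no real path solution)")
      }
      if (c1sq < t^2 - 1e-12) {
        infeasible("implied latent correlation |rho| exceeds 1")
      }
      if (c1sq > r2e + 1e-12) {
        infeasible("implied orthogonal environmental variance is negative")
      }
      c1 <- sqrt(c1sq) * sign(t)
      c2 <- sqrt(max(r2e - c1sq, 0))
      rho <- t / c1
    }
  } else {
    # single environmental latent; joint R2 implied by (R2_G, R2_E, rge)
    c1 <- sq_s; c2 <- 0; rho <- rge
    if (abs(rho) >= 1 && r2e > 0 && r2g > 0) infeasible("|rge| must be < 1")
    r2ge <- if (abs(rho) < 1) {
      (cg^2 + c1^2 - 2 * rho * cg * c1) / (1 - rho^2)
    } else {
      max(r2g, r2e)
    }
  }
  one_m_rho2 <- 1 - rho^2
  if (one_m_rho2 < 1e-12) {
    w_g <- cg; w_1 <- 0
  } else {
    w_g <- (cg - rho * c1) / one_m_rho2
    w_1 <- (c1 - rho * cg) / one_m_rho2
  }
  v_gxe <- if (is.null(cfg$gxe_effects)) 0 else sum(cfg$gxe_effects$coef^2)
  sigma2 <- 1 - r2ge - v_gxe
  if (sigma2 < -1e-12) {
    infeasible(sprintf(
      "outcome variance decomposition exceeds 1 (joint R2 %.3f + GxE variance %.3f)",
      r2ge, v_gxe))
  }
  sigma2 <- max(sigma2, 0)
  list(w_g = w_g, w_e1 = w_1, w_e2 = c2, rho = rho,
       c_g = cg, c_e1 = c1, c_e2 = c2, sigma2 = sigma2,
       r2_g = r2g, r2_e = r2e, r2_ge = r2ge, rge = rge, v_gxe = v_gxe)
}

solve_paths_from_props <- function(cfg) {
  rho <- cfg$rge
  pg <- if (is.null(cfg$prop_g_mediated)) 0 else cfg$prop_g_mediated
  if (abs(rho) < 1e-12 && pg > 0) {
    infeasible("nonzero prop_g_mediated requires nonzero rge")
  }
  # single latent E; b/w_g ratio from the mediated fraction of the G effect
  ratio <- if (pg <= 0) 0 else pg / (rho * (1 - pg))
  # scale so the joint latent R2 equals total_r2
  w_g <- 1; b <- ratio
  joint_unscaled <- w_g^2 + b^2 + 2 * rho * w_g * b
  k <- sqrt(cfg$total_r2 / joint_unscaled)
  w_g <- w_g * k; b <- b * k
  cg <- w_g + b * rho; c1 <- b + w_g * rho
  v_gxe <- if (is.null(cfg$gxe_effects)) 0 else sum(cfg$gxe_effects$coef^2)
  sigma2 <- 1 - cfg$total_r2 - v_gxe
  if (sigma2 < -1e-12) infeasible("outcome variance decomposition exceeds 1")
  list(w_g = w_g, w_e1 = b, w_e2 = 0, rho = rho,
       c_g = cg, c_e1 = c1, c_e2 = 0, sigma2 = max(sigma2, 0),
       r2_g = cg^2, r2_e = c1^2,
       r2_ge = if (abs(rho) < 1) (cg^2 + c1^2 - 2 * rho * cg * c1) / (1 - rho^2) else cg^2,
       rge = rho, v_gxe = v_gxe)
}

infeasible <- function(msg) {
  abort_polyenv(paste0("infeasible generator configuration: ", msg),
                class = "polyenv_feasibility_error")
}

#' Recompute population targets from a truth record
#'
#' Uses only the generating path coefficients (direct effects and the latent
#' correlation) stored in a score-tier truth record, and the variance algebra
#' of the three-latent outcome model, to recompute the population G-only,
#' E-only and joint R-squared and the population rGE. This is the analytic
#' route against which the generator's configured targets are checked.
#'
#' @param truth The `truth` element of a score-tier [simulate_score_cohort()]
#'   result.
#' @return A tibble with columns `r2_g`, `r2_e`, `r2_ge`, `rge`.
#' @export
analytic_targets <- function(truth) {
  p <- truth$paths
  cg <- p$w_g + p$w_e1 * p$rho
  c1 <- p$w_e1 + p$w_g * p$rho
  c2 <- p$w_e2
  s <- c1^2 + c2^2
  rge <- if (s > 0) p$rho * c1 / sqrt(s) else 0
  r2_ge <- if (abs(p$rho) < 1) {
    (cg^2 + c1^2 - 2 * p$rho * cg * c1) / (1 - p$rho^2) + c2^2
  } else {
    cg^2 + c2^2
  }
  tibble::tibble(r2_g = cg^2, r2_e = s, r2_ge = r2_ge, rge = rge)
}

#' Simulate study covariates
#'
#' Generates the covariate block used throughout the pipeline: age
#' (continuous), sex (binary), ten mutually orthogonal principal-component
#' style columns, and a genotyping-chip indicator (binary). PC columns are
#' built by QR orthogonalization of a Gaussian matrix, so they are exactly
#' orthogonal after centering.
#'
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param n_pcs Number of PC-like columns (default 10).
#' @return A tibble with columns `age`, `sex`, `pc1` ... `pc10`, `chip`.
#' @export
simulate_covariates <- function(n, seed = 1, n_pcs = 10) {
  n <- check_count(n, "n")
  set.seed(child_seed(seed, "covariates"))
  age <- rnorm(n, mean = 16, sd = 0.3)
  sex <- rbinom(n, 1, 0.5)
  z <- matrix(rnorm(n * n_pcs), n, n_pcs)
  z <- scale(z, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(z))
  pcs <- scale(q, center = TRUE, scale = FALSE)  # exactly orthogonal columns
  colnames(pcs) <- paste0("pc", seq_len(n_pcs))
  chip <- rbinom(n, 1, 0.5)
  dplyr::bind_cols(tibble::tibble(age = age, sex = sex),
                   tibble::as_tibble(pcs),
                   tibble::tibble(chip = chip))
}

#' Simulate a score-level cohort
#'
#' Generates the analysis-ready tier of the synthetic study: 20 observed
#' polygenic scores loading on a latent genetic composite, 13 environmental
#' measures (continuous composites plus binary life events thresholded from
#' latent normals) loading on the environmental composite, covariates, and a
#' continuous outcome combining direct genetic and environmental paths, a
#' genetically mediated environmental path (rGE), optional GxE product
#' effects, and Gaussian noise — scaled so the population R-squared of the
#' G-only, E-only and joint models and the population rGE equal the
#' configured targets exactly.
#'
#' @param config A [generator_config()].
#' @return An object of class `polyenv_cohort` with elements
#'   `data` (tibble: outcome, predictors, covariates), `roles` (tibble mapping
#'   column to role `gps` / `environment` / `covariate` / `outcome`), and
#'   `truth` (generating parameters, latent scores and analytic targets).
#' @export
simulate_score_cohort <- function(config) {
  stopifnot(inherits(config, "polyenv_config"))
  paths <- solve_score_paths(config)
  n <- config$n_individuals
  covariates <- simulate_covariates(n, seed = config$seed)

  set.seed(child_seed(config$seed, "latent"))
  g <- rnorm(n)
  e1 <- paths$rho * g + sqrt(max(1 - paths$rho^2, 0)) * rnorm(n)
  e2 <- rnorm(n)
  s <- paths$c_e1^2 + paths$c_e2^2
  e_hat <- if (s > 0) (paths$c_e1 * e1 + paths$c_e2 * e2) / sqrt(s) else rep(0, n)

  cov_mat <- as.matrix(covariates)
  cov_mat <- scale(cov_mat)

  n_env <- config$n_env_continuous + config$n_env_binary
  set.seed(child_seed(config$seed, "gps"))
  w_cov <- matrix(rnorm(ncol(cov_mat) * (config$n_gps + n_env + 1)),
                  ncol(cov_mat)) * config$covariate_effect
  lam_g <- config$gps_loading
  gps <- sapply(seq_len(config$n_gps), function(k) {
    lam_g * g + cov_mat %*% w_cov[, k] + sqrt(1 - lam_g^2) * rnorm(n)
  })
  colnames(gps) <- paste0("gps_", sprintf("%02d", seq_len(config$n_gps)))

  set.seed(child_seed(config$seed, "env"))
  env <- matrix(0, n, n_env)
  env_names <- character(n_env)
  lam_e <- config$env_loading
  for (j in seq_len(config$n_env_continuous)) {
    env[, j] <- lam_e * e_hat + cov_mat %*% w_cov[, config$n_gps + j] +
      sqrt(1 - lam_e^2) * rnorm(n)
  }
  env_names[seq_len(config$n_env_continuous)] <-
    if (config$n_env_continuous == 2) c("ses", "chaos") else
      paste0("env_", sprintf("%02d", seq_len(config$n_env_continuous)))
  endorsement <- numeric(0)
  if (config$n_env_binary > 0) {
    lam_b <- config$binary_loading
    endorsement <- seq(config$endorsement_range[2], config$endorsement_range[1],
                       length.out = config$n_env_binary)
    cov_var <- colSums(w_cov^2)  # population variance of the covariate part
    for (b in seq_len(config$n_env_binary)) {
      j <- config$n_env_continuous + b
      latent <- lam_b * e_hat + cov_mat %*% w_cov[, config$n_gps + j] +
        sqrt(1 - lam_b^2) * rnorm(n)
      sd_lat <- sqrt(1 + cov_var[config$n_gps + j])
      thr <- qnorm(1 - endorsement[b]) * sd_lat
      env[, j] <- as.integer(latent > thr)
      env_names[j] <- paste0("life_event_", sprintf("%02d", b))
    }
  }
  colnames(env) <- env_names

  set.seed(child_seed(config$seed, "outcome"))
  y_core <- paths$w_g * g + paths$w_e1 * e1 + paths$w_e2 * e2
  gxe_cols <- NULL
  if (!is.null(config$gxe_effects) && nrow(config$gxe_effects) > 0) {
    gxe_cols <- matrix(0, n, nrow(config$gxe_effects))
    for (i in seq_len(nrow(config$gxe_effects))) {
      gi <- config$gxe_effects$gps[i]; ei <- config$gxe_effects$env[i]
      prod_term <- as.numeric(scale(gps[, gi])) * as.numeric(scale(env[, ei]))
      gxe_cols[, i] <- as.numeric(scale(prod_term))
      y_core <- y_core + config$gxe_effects$coef[i] * gxe_cols[, i]
    }
  }
  y <- y_core + sqrt(paths$sigma2) * rnorm(n) +
    cov_mat %*% w_cov[, config$n_gps + n_env + 1]

  mediation <- latent_mediation_truth(paths)
  truth <- list(
    paths = paths[c("w_g", "w_e1", "w_e2", "rho", "sigma2")],
    targets = tibble::tibble(r2_g = paths$r2_g, r2_e = paths$r2_e,
                             r2_ge = paths$r2_ge, rge = paths$rge),
    mediation = mediation,
    latents = tibble::tibble(g = g, e1 = e1, e2 = e2, e_hat = e_hat),
    gxe = config$gxe_effects,
    gxe_terms = gxe_cols,
    loadings = list(gps = config$gps_loading, env = config$env_loading,
                    binary = config$binary_loading),
    endorsement = endorsement,
    seed = config$seed
  )
  data <- dplyr::bind_cols(
    tibble::tibble(outcome = as.numeric(y)),
    tibble::as_tibble(gps), tibble::as_tibble(env), covariates
  )
  roles <- tibble::tibble(
    column = names(data),
    role = c("outcome", rep("gps", config$n_gps), rep("environment", n_env),
             rep("covariate", ncol(covariates)))
  )
  structure(list(data = data, roles = roles, truth = truth, config = config),
            class = "polyenv_cohort")
}

# Population mediation decomposition on the latent composites (X = G,
# M = standardized E prediction, or the reverse orientation).
latent_mediation_truth <- function(paths) {
  cg <- paths$c_g
  sq_s <- sqrt(paths$c_e1^2 + paths$c_e2^2)
  rge <- paths$rge
  denom <- 1 - rge^2
  bcp_g <- if (denom > 0) (cg - rge * sq_s) / denom else NA_real_
  bcp_e <- if (denom > 0) (sq_s - rge * cg) / denom else NA_real_
  tibble::tibble(
    orientation = c("G_via_E", "E_via_G"),
    beta_c = c(cg, sq_s),
    beta_c_prime = c(bcp_g, bcp_e),
    indirect = beta_c - beta_c_prime,
    proportion_mediated = ifelse(abs(beta_c) > 1e-12, indirect / beta_c, NA_real_)
  )
}

#' @export
print.polyenv_cohort <- function(x, ...) {
  tier <- if (!is.null(x$genotypes)) "SNP tier" else "score tier"
  cat(sprintf("<polyenv_cohort: %s, n = %d>\n", tier, nrow(x$data)))
  if (!is.null(x$truth$targets)) {
    t <- x$truth$targets
    cat(sprintf("  population targets: R2_G = %.3f, R2_E = %.3f, R2_G+E = %.3f, rGE = %.3f\n",
                t$r2_g, t$r2_e, t$r2_ge, t$rge))
  }
  invisible(x)
}

#' Simulate a SNP-level mini-cohort with LD blocks and summary statistics
#'
#' Generates genotypes in blocks of autoregressive linkage disequilibrium
#' (latent haplotype correlation `ld_rho`), a phenotype driven by a fixed set
#' of causal SNPs, and GWAS-style per-SNP phenotype-genotype correlations
#' computed on an *independently simulated discovery replicate* of the same
#' generative process — mirroring the two-sample design in which summary
#' statistics come from an external GWAS, never from the analysis cohort.
#'
#' @param config A [generator_config()]; `n_snps` must divide evenly into
#'   `n_ld_blocks`.
#' @return A `polyenv_cohort` with elements `genotypes` (n x m allele-count
#'   matrix), `phenotype`, `summary_stats` (tibble: snp, a1, a2, r, n),
#'   `blocks` (tibble: block, start, end), `maf`, and `truth` (causal indices
#'   and effect sizes).
#' @export
simulate_snp_cohort <- function(config) {
  stopifnot(inherits(config, "polyenv_config"))
  m <- config$n_snps; n_blocks <- config$n_ld_blocks
  if (m %% n_blocks != 0) {
    abort_polyenv("`n_snps` must be divisible by `n_ld_blocks`.",
                  class = "polyenv_config_error")
  }
  block_size <- m %/% n_blocks
  set.seed(child_seed(config$seed, "snp"))
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  snp_ids <- paste0("rs", sprintf("%05d", seq_len(m)))
  allele_pool <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  alleles <- allele_pool[sample.int(4L, m, replace = TRUE)]
  a1 <- vapply(alleles, `[`, "", 1L)
  a2 <- vapply(alleles, `[`, "", 2L)
  causal <- integer(0)
  if (config$causal_per_block > 0) {
    causal <- unlist(lapply(seq_len(n_blocks), function(b) {
      (b - 1L) * block_size + sample.int(block_size, config$causal_per_block)
    }))
  }
  effects <- rep(0, m)
  if (length(causal) > 0 && config$snp_h2 > 0) {
    raw <- rnorm(length(causal))
    effects[causal] <- raw / sqrt(sum(raw^2)) * sqrt(config$snp_h2)
  }

  blocks <- tibble::tibble(
    block = seq_len(n_blocks),
    start = (seq_len(n_blocks) - 1L) * block_size + 1L,
    end = seq_len(n_blocks) * block_size
  )

  sim_geno <- function(n) {
    geno <- matrix(0L, n, m)
    for (b in seq_len(n_blocks)) {
      idx <- blocks$start[b]:blocks$end[b]
      for (hap in 1:2) {
        z <- matrix(rnorm(n * block_size), n, block_size)
        for (j in seq_along(idx)[-1]) {
          z[, j] <- config$ld_rho * z[, j - 1] +
            sqrt(1 - config$ld_rho^2) * z[, j]
        }
        thr <- qnorm(maf[idx])
        geno[, idx] <- geno[, idx] +
          (z < matrix(thr, n, block_size, byrow = TRUE))
      }
    }
    storage.mode(geno) <- "integer"
    colnames(geno) <- snp_ids
    geno
  }
  sim_pheno <- function(geno) {
    if (all(effects == 0)) return(rnorm(nrow(geno)))
    xs <- scale(geno)
    xs[is.nan(xs)] <- 0
    as.numeric(xs %*% effects) + rnorm(nrow(geno)) * sqrt(1 - config$snp_h2)
  }

  genotypes <- sim_geno(config$n_individuals)
  set.seed(child_seed(config$seed, "phenotype"))
  phenotype <- sim_pheno(genotypes)

  set.seed(child_seed(config$seed, "discovery"))
  geno_d <- sim_geno(config$n_discovery)
  y_d <- sim_pheno(geno_d)
  r <- as.numeric(cor(geno_d, y_d))
  r[is.na(r)] <- 0
  summary_stats <- tibble::tibble(
    snp = snp_ids, a1 = a1, a2 = a2, r = r, n = config$n_discovery
  )

  structure(list(
    data = tibble::tibble(outcome = phenotype),
    genotypes = genotypes, phenotype = phenotype,
    summary_stats = summary_stats, blocks = blocks, maf = maf,
    truth = list(causal = causal, effects = effects, h2 = config$snp_h2,
                 seed = config$seed),
    config = config
  ), class = "polyenv_cohort")
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes the predictor/outcome table as TSV, summary statistics as TSV
#' (columns snp, a1, a2, r, n), genotypes as a TSV matrix, LD blocks as a
#' 3-column interval table, column roles as TSV, and the truth record
#' (scalar generating parameters) as JSON.
#'
#' @param cohort A `polyenv_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "polyenv_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
  }
  wr(cohort$data, "panel.tsv")
  if (!is.null(cohort$roles)) wr(cohort$roles, "roles.tsv")
  if (!is.null(cohort$summary_stats)) wr(cohort$summary_stats, "summary_stats.tsv")
  if (!is.null(cohort$genotypes)) wr(as.data.frame(cohort$genotypes), "genotypes.tsv")
  if (!is.null(cohort$blocks)) wr(cohort$blocks, "blocks.tsv")
  truth_path <- file.path(dir, "truth.json")
  scalar_truth <- cohort$truth[!vapply(cohort$truth, is.matrix, TRUE)]
  scalar_truth$latents <- NULL
  scalar_truth$gxe_terms <- NULL
  jsonlite::write_json(scalar_truth, truth_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(c(written, truth_path))
}
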