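test_that("generator config validates ranges and feasibility", {
  expect_s3_class(generator_config(), "polyenv_config")
  expect_error(generator_config(rge = 1.2), class = "polyenv_config_error")
  expect_error(generator_config(maf_range = c(0, 0.5)),
               class = "polyenv_config_error")
  expect_error(generator_config(n_gps = -1), class = "polyenv_config_error")
  expect_error(generator_config(prop_g_mediated = 1.4),
               class = "polyenv_config_error")
  # a variance budget over 1 is refused with an explicit feasibility error
  expect_error(
    generator_config(target_r2 = c(G = 0.5, E = 0.6, GE = 0.9),
                     gxe_effects = data.frame(gps = 1, env = 1, coef = 0.5)),
    class = "polyenv_feasibility_error")
  # joint R2 below a marginal is impossible
  expect_error(generator_config(target_r2 = c(G = 0.2, E = 0.3, GE = 0.25)),
               class = "polyenv_feasibility_error")
  # with rge = 0 the joint target must be additive
  expect_error(generator_config(rge = 0, target_r2 = c(G = .2, E = .3, GE = .4)),
               class = "polyenv_feasibility_error")
  expect_silent(generator_config(rge = 0, target_r2 = c(G = .2, E = .3, GE = .5)))
})

test_that("score-tier generator is deterministic and complete", {
  a <- tiny_cohort(n = 400, seed = 42)
  b <- tiny_cohort(n = 400, seed = 42)
  expect_identical(a$data, b$data)
  expect_false(anyNA(a$data))
  c2 <- tiny_cohort(n = 400, seed = 43)
  expect_false(identical(a$data$outcome, c2$data$outcome))
  expect_equal(nrow(a$data), 400)
  # 20 gps + 13 env + 13 covariates + outcome
  expect_equal(ncol(a$data), 1 + 20 + 13 + 13)
  le <- unlist(a$data[paste0("life_event_", sprintf("%02d", 1:11))])
  expect_true(all(le %in% 0:1))
})

test_that("analytic targets recomputed from the truth record match the config", {
  coh <- tiny_cohort(n = 200, seed = 9)
  at <- analytic_targets(coh$truth)
  expect_equal(at$r2_g, 0.18, tolerance = 1e-6)
  expect_equal(at$r2_e, 0.30, tolerance = 1e-6)
  expect_equal(at$r2_ge, 0.36, tolerance = 1e-6)
  expect_equal(at$rge, 0.38, tolerance = 1e-6)
  # and for other presets, including an implied joint R2
  cfg2 <- generator_config(n_individuals = 200, rge = -0.2,
                           target_r2 = c(G = 0.1, E = 0.25), seed = 2)
  coh2 <- simulate_score_cohort(cfg2)
  at2 <- analytic_targets(coh2$truth)
  expect_equal(at2$r2_g, 0.1, tolerance = 1e-6)
  expect_equal(at2$r2_e, 0.25, tolerance = 1e-6)
  expect_equal(at2$rge, -0.2, tolerance = 1e-6)
})

test_that("monte-carlo moments converge to the analytic targets", {
  coh <- tiny_cohort(n = 50000, seed = 31)
  tr <- coh$truth
  lat <- tr$latents
  # empirical latent-composite correlation
  expect_lt(abs(cor(lat$g, lat$e_hat) - 0.38), 0.01)
  # empirical population R2 of the latent G and E predictions; the targets
  # are defined conditional on covariates, so strip their contribution first
  covs <- as.matrix(coh$data[coh$roles$column[coh$roles$role == "covariate"]])
  y <- as.numeric(residualize(cbind(y = coh$data$outcome), covs))
  r2 <- function(pred) cor(pred, y)^2
  expect_lt(abs(r2(lat$g) - 0.18), 0.01)
  expect_lt(abs(r2(lat$e_hat) - 0.30), 0.01)
})

test_that("zero-rge preset gives uncorrelated composites", {
  cfg <- generator_config(n_individuals = 5000, rge = 0,
                          target_r2 = c(G = 0.18, E = 0.30), seed = 17)
  coh <- simulate_score_cohort(cfg)
  expect_lt(abs(cor(coh$truth$latents$g, coh$truth$latents$e_hat)), 0.05)
})

test_that("planted GxE coefficients are recovered by OLS on the truth record", {
  cfg <- generator_config(
    n_individuals = 10000, seed = 23,
    gxe_effects = data.frame(gps = 1, env = 1, coef = 0.3))
  coh <- simulate_score_cohort(cfg)
  d <- coh$data
  prod_term <- coh$truth$gxe_terms[, 1]
  fit <- lm(d$outcome ~ d$gps_01 + d$ses + prod_term)
  expect_equal(unname(coef(fit)["prod_term"]), 0.3, tolerance = 0.05)
})

test_that("covariate simulation has the documented shape and orthogonal PCs", {
  cv <- simulate_covariates(100, seed = 4)
  expect_equal(dim(cv), c(100L, 13L))
  pcs <- as.matrix(cv[paste0("pc", 1:10)])
  cors <- cor(pcs)
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-10)
  expect_identical(cv, simulate_covariates(100, seed = 4))
  expect_error(simulate_covariates(0), class = "polyenv_config_error")
})

test_that("SNP-tier generator: determinism, LD blocks, discovery independence", {
  cfg <- generator_config(n_individuals = 250, n_snps = 40, n_ld_blocks = 4,
                          n_discovery = 800, seed = 12)
  a <- simulate_snp_cohort(cfg)
  b <- simulate_snp_cohort(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_true(all(a$genotypes %in% 0:2))
  expect_equal(nrow(a$summary_stats), 40)
  expect_true(all(abs(a$summary_stats$r) <= 1))
  # neighbouring SNPs in a block are in LD
  g <- scale(a$genotypes)
  adj <- sapply(1:9, function(j) cor(g[, j], g[, j + 1]))
  expect_gt(mean(adj), 0.25)
  # summary stats differ from correlations computed on the emitted cohort
  own_r <- as.numeric(cor(a$genotypes, a$phenotype))
  expect_gt(max(abs(own_r - a$summary_stats$r)), 1e-4)
  expect_error(
    simulate_snp_cohort(generator_config(n_snps = 41, n_ld_blocks = 4)),
    class = "polyenv_config_error")
})

test_that("null SNP model: discovery correlations shrink with discovery n", {
  r_abs <- sapply(c(400, 6400), function(nd) {
    cfg <- generator_config(n_individuals = 100, n_snps = 20, n_ld_blocks = 2,
                            n_discovery = nd, snp_h2 = 0, seed = 5)
    mean(abs(simulate_snp_cohort(cfg)$summary_stats$r))
  })
  expect_lt(r_abs[2], r_abs[1])
  expect_lt(r_abs[2], 0.03)
})

test_that("causal SNPs carry the strongest discovery signal in most blocks", {
  hits <- 0; total <- 0
  for (s in 1:20) {
    cfg <- generator_config(n_individuals = 50, n_snps = 30, n_ld_blocks = 3,
                            n_discovery = 4000, snp_h2 = 0.5, seed = s)
    coh <- simulate_snp_cohort(cfg)
    for (b in 1:3) {
      idx <- coh$blocks$start[b]:coh$blocks$end[b]
      top <- idx[which.max(abs(coh$summary_stats$r[idx]))]
      causal_b <- intersect(coh$truth$causal, idx)
      total <- total + 1
      # the top SNP should be the causal one or an immediate LD neighbour
      hits <- hits + (abs(top - causal_b) <= 1)
    }
  }
  expect_gt(hits / total, 0.8)
})

test_that("cohorts round-trip to plain-text files", {
  withr::with_tempdir({
    coh <- tiny_cohort(n = 120, seed = 3)
    files <- write_cohort(coh, "out")
    expect_true(all(file.exists(files)))
    back <- utils::read.delim(file.path("out", "panel.tsv"))
    expect_equal(dim(back), dim(coh$data))
    expect_equal(back$outcome, coh$data$outcome, tolerance = 1e-12)
    truth <- jsonlite::read_json(file.path("out", "truth.json"))
    expect_equal(truth$paths$rho, coh$truth$paths$rho, tolerance = 1e-12)
  })
})
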