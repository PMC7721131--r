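---
title: "Modelling gene-environment interplay in the prediction of a complex trait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gene-environment interplay in the prediction of a complex trait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Educational achievement — like most complex behavioural traits — is
predicted both by genome-wide polygenic scores (GPS) and by measured
environments, and the two sources of prediction are not independent:
genetic propensity correlates with exposure (gene-environment correlation,
rGE), environments can mediate genetic effects, and genetic confounding can
inflate apparent environmental effects. `polyenv` implements a joint
multivariable pipeline for quantifying this interplay:

1. **GPS construction** from GWAS summary statistics with an LD-block
   reference panel (a lassosum-style penalized regression).
2. **Joint penalized prediction**: elastic-net models using environments
   only (E), polygenic scores only (G), or both (G+E), tuned by repeated
   10-fold cross-validation and evaluated by hold-out R².
3. **Bootstrapped nested-model comparison** of hold-out R².
4. **Post-selection inference** on the selected predictors (naive,
   hold-out, and conditional truncated-normal estimates).
5. **rGE and mediation decomposition** of the model prediction composites.
6. **Hierarchical group-lasso discovery of two-way interactions** under
   strong hierarchy, with GxE terms reintroduced into the elastic net.

Because individual-level cohort data of this kind are access-restricted,
the package ships a calibrated synthetic-cohort generator
(`simulate_score_cohort()`, `simulate_snp_cohort()`) that emulates the
statistical structure of such a study, so every stage is exercised by
reproducible simulation.

# The synthetic cohort generator

## Score tier

The score-level generator draws three standard-normal latents: a genetic
composite $G$, an environmental latent $E_1$ with $\mathrm{cor}(G, E_1) =
\rho$, and an independent environmental latent $E_2$. The outcome is

$$y = w_g G + w_1 E_1 + w_2 E_2 \; (+\ \text{GxE products}) + \varepsilon .$$

Writing $c_g, c_1, c_2$ for the covariances of $y$ with the latents, the
population quantities of interest are

* $R^2_G = c_g^2$ (G-only model),
* $R^2_E = c_1^2 + c_2^2$ (E-only model, which can use both latents),
* $r_{GE} = \rho\, c_1 / \sqrt{R^2_E}$ (correlation of $G$ with the
  population E-model prediction $\hat E \propto c_1 E_1 + c_2 E_2$),
* $R^2_{G+E} = \frac{c_g^2 + c_1^2 - 2\rho c_g c_1}{1-\rho^2} + c_2^2$.

With a *single* environmental latent these four quantities are mutually
constrained — three of them determine the fourth — so a preset that fixes
all four (the default preset uses $R^2_G = .18$, $R^2_E = .30$,
$R^2_{G+E} = .36$, $r_{GE} = .38$) would be unattainable. Splitting the
environmental signal into a $G$-correlated part and a $G$-orthogonal part
adds exactly one degree of freedom, and the system solves in closed form:

$$c_1^2 = \frac{t^2 (R^2_E - R^2_{G+E})}{(c_g - t)^2 + (R^2_E - R^2_{G+E})},
  \qquad t = r_{GE}\sqrt{R^2_E},$$

with $\rho = t / c_1$ and $c_2^2 = R^2_E - c_1^2$. `generator_config()`
refuses configurations with no real solution (for example a joint R² below
a marginal R², or an outcome variance decomposition exceeding 1), naming
the violated constraint. `analytic_targets()` recomputes the four
quantities from the stored path coefficients; the generator's tests verify
agreement with the configured targets to $10^{-6}$ and Monte-Carlo
convergence at $n = 50{,}000$ within $\pm 0.01$.

A satisfying property of this calibration is that the implied population
mediation decomposition on the latent composites —
$\beta_C = c_g = .424$ reduced to
$\beta_{C'} = (c_g - r_{GE}\sqrt{R^2_E})/(1-r_{GE}^2) = .253$ (about 40%
environmentally mediated), and $\beta_C = \sqrt{R^2_E} = .548$ reduced to
$.452$ (about 18% genetically confounded) — emerges from the R²/rGE
targets alone. The truth record stores these implied proportions. For the
same reason the `prop_g_mediated` / `prop_e_confounded` configuration
fields only drive the path solve when no `target_r2` is supplied: with
R² targets present the mediation proportions are already pinned down.

Observed variables are noisy indicators of the latents: 20 GPS load on $G$
(default loading 0.6), two continuous environmental composites (an SES-like
and a household-chaos-like score) load on $\hat E$ (loading 0.8), and 11
binary life events are thresholded latent normals (loading 0.6) with
endorsement rates spread over a configurable range (default 5–50%).
Loadings in the 0.6–0.8 range correspond to indicator reliabilities typical
of composite measures in this literature; they were fixed once, before any
downstream evaluation, and are deliberately below 1 so that the observable
panels recover only part of the latent-scale R² (an attenuation every real
study faces). Covariates (age, sex, 10 orthogonalized PCs, genotyping chip)
are mixed into every observed column with small random weights
(`covariate_effect`), which makes the residualization step consequential;
the population calibration is defined *conditional on covariates*, i.e. on
the residualized scale the pipeline actually analyses.

GxE product effects are added as standardized products of the named
observed indicator pair, so a configured coefficient is recoverable by
regression of the outcome on the product term adjusting for the mains.

What the generator does **not** emulate: realistic human LD maps, ancestry
structure, family/twin clustering, missing data, and heavy-tailed outcomes
(the outcome is rank-inverse-normal transformed downstream anyway). Tests
passing on this generator show the machinery is correct and calibrated,
not that real-data effect sizes will replicate.

## SNP tier

The SNP-level generator exists to test GPS construction at desk scale. It
draws haplotypes with within-block autoregressive latent correlation
(`ld_rho`, default 0.7), thresholds them at per-SNP minor-allele
frequencies, and sums two haplotypes into allele counts. One causal SNP per
block (configurable) carries the phenotype signal (`snp_h2`, default 0.3).
Crucially, summary statistics are per-SNP phenotype–genotype correlations
computed on an **independently simulated discovery replicate** of the same
generative process, never on the emitted cohort — mirroring the two-sample
design of real GPS analyses and preventing artificial overfitting in tests.

Seed policy: one master seed; each stage (covariates, latents, indicators,
outcome, split, SNP draw, discovery replicate) uses a child seed derived by
a fixed documented offset, so identical configuration plus seed yields
bit-identical output.

# Methods and numerical choices

## Summary-statistic polygenic scoring

`lassosum_fit()` minimizes, up to a constant,

$$(1-s)\,\beta^\top R\,\beta - 2\beta^\top r + s\,\beta^\top\beta
  + 2\lambda\lVert\beta\rVert_1,$$

where $r$ holds per-SNP phenotype correlations and $R$ is the
block-diagonal LD correlation matrix of a reference panel, by blockwise
cyclic coordinate descent (compiled kernel). Because the diagonal of $R$ is
1, each coordinate update is a soft-threshold with unit denominator; at
$s = 1$ the LD term vanishes and the solution is the elementwise
soft-threshold of $r$, and at $\lambda = 0, s = 1$ it is $r$ itself — both
used as exact oracles in the tests, alongside a brute-force minimizer on
8-SNP blocks. Convergence is declared when the largest coefficient change
falls below $10^{-7}$ (at most 10,000 sweeps), comfortably inside the
$10^{-5}$ oracle tolerance. Allele alignment follows the standard
convention: flip the sign of $r$ when effect/other alleles are swapped
relative to the reference, drop strand-ambiguous (A/T, C/G) and
irreconcilable SNPs. `tune_gps()` scans a $(\lambda, s)$ grid against a
tuning phenotype, maximizing squared correlation; all-zero solutions score
0 rather than erroring. The package does not attempt pseudovalidation or
cross-chromosome LD.

## Elastic-net prediction models

`enet_fit()` minimizes the $1/(2n)$-scaled elastic net

$$\tfrac{1}{2n}\lVert y - X\beta\rVert^2
 + \lambda\big(\alpha\lVert\beta\rVert_1
 + \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\big)$$

by cyclic coordinate descent on Gram sufficient statistics. The $1/(2n)$
convention (rather than the unscaled residual sum of squares) keeps
$\lambda$ stable across sample sizes; it is a monotone reparameterization
of the same objective. `repeated_cv()` implements 10-fold cross-validation
repeated (by default) 100 times, minimizing RMSE; standardization is refit
inside each training fold so no evaluation information leaks into scaling.
The default path is 100 log-spaced $\lambda$ values from $\lambda_{\max}$
(smallest value zeroing all coefficients) down to $0.001\,\lambda_{\max}$,
with $\alpha \in \{0.1, \dots, 1.0\}$; exact RMSE ties go to larger
$\lambda$, then larger $\alpha$ (the sparser model). Hold-out performance
is $R^2 = 1 - SSE/SST$ with $SST$ around the hold-out mean.

## Preprocessing

`prepare_panel()` chains the study conventions: a rank-based inverse
normal transform of the outcome using the Blom offset
$(\mathrm{rank} - 3/8)/(n + 1/4)$ with averaged ties (the offset is a
choice; the transform itself only names the family), residualization of
the outcome and all predictors on age, sex, 10 PCs and chip, a random
80/20 train/hold-out split, and standardization using training-set moments
applied unchanged to the hold-out rows (the leakage-safe reading of an
otherwise unstated convention). Binary items are residualized and
standardized like continuous ones — one uniform treatment of all
variables. Inputs with missing cells are rejected with a clear error;
missing-data handling is out of scope. Composite construction
(`build_ses_composite()`: mean of five standardized measures;
`build_chaos_score()`: mean of six 3-point items with items 1, 4, 6
reverse-coded) and life-event filtering (`filter_life_events()`: labelled
exclusions first, then items endorsed by fewer than 100 people) are
provided as the measurement-side utilities.

## Bootstrap comparison

`bootstrap_r2()` draws hold-out rows with replacement — the same indices
for every model, so nested differences are paired — and recomputes R² per
draw with the *fitted models held fixed*. Refitting per resample would
contradict the hold-out framing of the evaluation; this evaluation-only
reading is interpretive and stated here deliberately. Intervals are
percentile (2.5th/97.5th), and a nested difference is called significant
when its interval excludes zero. Resamples with zero outcome variance are
recorded as missing and counted, not silently dropped.

## Post-selection inference

For the predictors selected by an L1-penalized fit at fixed $\lambda$,
`selective_inference()` characterizes the selection event (active set and
signs) as a polyhedron $\{Ay \le b\}$, from which each selected-model OLS
coefficient is distributed as a truncated normal
$TN_{[a,b]}(\beta, \tau^2)$ with bounds determined by the data and the
selection. Three implementation choices:

* the elastic-net case ($\alpha < 1$) is reduced to a lasso-shaped event by
  absorbing the ridge component into the active-block Gram matrix — the
  standard augmented-data reduction, documented as an approximation;
* $\sigma^2$ is estimated from selected-model OLS residuals in the
  training set;
* truncated-normal tail probabilities are computed through log-scale
  normal tails, so extreme truncation bounds do not underflow.

Degenerate truncation (observed value at a boundary) yields a flagged
estimate with an infinite interval rather than a failure. Conditional
confidence intervals invert the truncated-normal CDF in its mean by root
finding. Under a global-null simulation the conditional p-values of
selected variables are uniform (a property test), while naive training-set
p-values are anti-conservative; hold-out OLS is valid but wider.

## rGE and mediation

`rge_correlation()` is the Pearson correlation of the hold-out predicted
values from the G and E models, with a paired percentile bootstrap.
`mediate()` fits the saturated linear mediation triangle as two/three OLS
regressions; in this linear case the difference of coefficients equals the
product of coefficients exactly (asserted to $10^{-10}$), and a full SEM
engine would add nothing. Unlike the model-comparison bootstrap, the
mediation bootstrap *refits all paths* on every resample, because here the
resampling uncertainty of the path estimates is the target. Proportion
mediated $(\beta_C - \beta_{C'})/\beta_C$ is reported as undefined when
the total effect is below tolerance. `run_both_orientations()` runs the
decomposition with E mediating G (environmental mediation) and with G
mediating E — statistically equivalent in the linear case, interpreted as
genetic confounding.

## Interaction discovery

`fit_hierarchical()` implements a glinternet-style overlapped group lasso:
each of the $p(p-1)/2$ candidate pairs contributes a three-coefficient
group (both member columns and their re-standardized product), mains keep
their own L1 terms, and pair groups are penalized with weight $\sqrt{3}$
(square-root of group size) so mains-only and pair groups are comparably
penalized. A pair can then only enter through a group that also carries
its two main effects — strong hierarchy holds by construction. All
predictors are continuous or standardized binary, so glinternet's
categorical machinery is unnecessary and not implemented.

The solver is monotone FISTA (proximal gradient with momentum and a
monotonicity safeguard) on Gram sufficient statistics, with stopping
governed by the Karush-Kuhn-Tucker stationarity residual — a direct
optimality certificate for this convex objective, checked in tests at
$10^{-6}$ together with objective dominance over a generic numerical
minimizer. Because the duplicated design columns make coefficients
non-identifiable (only fitted values and the objective are unique), oracle
comparisons are on objective value and fit, not raw coefficients.
$\lambda$ is chosen by 10-fold cross-validation (one repeat, matching the
lighter tuning used for interaction scans); the default selection rule is
the one-standard-error rule, the conservative standard for sparse
selection — the minimum-MSE rule tends to admit spurious low-weight pairs
in null simulations and is available as `rule = "min"`. Cross-validation
path fits use a relaxed tolerance (`cv_tol`, default $10^{-5}$) since
lambda selection does not need the final fit's precision.

Discovered GxE pairs are reintroduced into the elastic net by
`refit_with_gxe()` (products of standardized columns, re-standardized),
and the G+E versus G+E+GxE comparison is delegated to the bootstrap
machinery.

# Problem sizes used in the shipped checks

The package's own test-and-demonstration runs use the calibrated preset at
the study scale ($n = 7026$, 33 predictors, 80/20 split) with reduced
tuning (e.g. cross-validation repeats 5 instead of 100, a 15–20 value
lambda path, 100 pipeline replicates, bootstrap $B$ between 200 and 1000),
and smaller designs for solver oracles and calibration studies (e.g.
$p = 10$, $n = 200$, 500 replicates for selective-inference uniformity;
$n = 2000$ for planted-interaction recovery). These sizes were chosen as
the smallest at which the targeted properties are statistically decisive;
the estimators themselves default to the full-size settings
(100 repeats, $B = 1000$).

# Known limitations

* The generator's exchangeable within-set indicator correlations are a
  free design choice; real GPS panels and environment batteries have
  richer correlation structure.
* Conditional inference conditions on the active set and signs at the
  chosen penalty; multi-lambda selection events, data carving and
  FDR-controlling selective procedures are out of scope.
* The hierarchical scan considers two-way interactions only, under strong
  hierarchy; weak-hierarchy variants are not implemented.
* Mediation here is a statistical decomposition of prediction composites;
  no causal identification is claimed, and within-family designs that
  could strengthen interpretation are out of scope.
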