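---
title: "Methods: sparse penalized logistic mixed models for structured cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse penalized logistic mixed models for structured cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Genome-wide variable selection for a binary trait faces two entangled
difficulties: the design is high-dimensional (many more SNPs than samples),
and the samples are not exchangeable — relatedness and population structure
induce a correlation pattern that, if ignored, both inflates false
selections (structure-stratified allele frequencies masquerade as signal)
and degrades prediction. The standard fixed-effect remedy, adding a few
principal components of the genotype matrix as covariates, is brittle when
the number of structure dimensions exceeds the number of PCs used.

`pglmmlasso` fits a logistic mixed model with a lasso penalty on the SNP
effects:

$$\operatorname{logit}(\mu_i) = X_i^\top \alpha + G_i^\top \beta + b_i,
\qquad b \sim N(0, \textstyle\sum_s \tau_s V_s),$$

where $X$ holds unpenalized covariates (intercept, age, sex, optionally
PCs), $G$ holds standardized SNP dosages, and $V_1$ is the genetic
relationship matrix (GRM) estimated from a genome-wide panel. The random
effect absorbs confounding along *every* eigendirection of the GRM, shrunk
smoothly by eigenvalue, instead of a hard cutoff at some number of PCs.

# Two-stage estimation

## Stage 1: null-model variance components (`fit_null_pglmm`)

The variance components are estimated once under the null of no SNP effects
($\beta = 0$) and then held fixed along the whole regularization path —
the "population parameters previously determined" (P3D) strategy that makes
the path computationally feasible.

Fitting uses penalized quasi-likelihood: the Bernoulli response is
linearized into a working response
$\tilde Y = \eta + (y - \mu)/W$ with IRLS weights $W = \mu(1-\mu)$, and the
working linear mixed model
$\tilde Y = X\alpha + b + \varepsilon,\ \varepsilon \sim N(0, W^{-1})$
is fitted by average-information REML. Each outer iteration computes
$\Sigma = W^{-1} + \sum_s \tau_s V_s$, the REML projection
$P = \Sigma^{-1} - \Sigma^{-1}X(X^\top\Sigma^{-1}X)^{-1}X^\top\Sigma^{-1}$,
the score $\tfrac12(\tilde Y^\top P V_s P \tilde Y - \operatorname{tr} P V_s)$
and the average-information matrix, takes a Newton step with step-halving,
clamps $\tau_s \ge 10^{-6}\operatorname{Var}(\tilde Y)$, updates
$\alpha$ and the BLUP $b$, and refreshes the working response.
Convergence requires both a small relative parameter change
(tolerance $10^{-5}$) and a small REML score *at the returned state*
(one-sided when a component sits at its clamp, where the boundary
condition only requires the score to be non-positive).

A caveat worth knowing: like all PQL estimators for Bernoulli data, the
variance component is attenuated relative to exact maximum likelihood,
increasingly so for small cluster sizes. The package's Monte-Carlo checks
use shared-intercept families of size 10, where the linearization is
accurate; for very sparse relatedness the absolute value of $\hat\tau$
should be interpreted cautiously (its role here is regularization, not
heritability estimation).

## Stage 2: the penalized path (`pglmm_path`)

A quadratic bound on the logistic curvature, $\mu(1-\mu) \le 1/4$, replaces
the iteration-dependent covariance $W^{-1} + \hat\tau V$ by the *fixed*
surrogate $\Sigma_b = cI + \hat\tau V$ with $c = 4$. One eigendecomposition
$\hat\tau V = U \operatorname{diag}(d) U^\top$ then diagonalizes the whole
problem: rotating by $U^\top$ gives independent observations with weights
$w_i = 1/(c + d_i)$, and the random effect can be profiled out exactly,
leaving a weighted lasso on the rotated design with per-eigencomponent
shrinkage factors $s_i = d_i/(c + d_i)$. The bound working response is
$\tilde Y_b = \eta + c\,(y - \mu)$.

Each $\lambda$ on a log-spaced grid (default 100 values down to
$0.01\,\lambda_{\max}$) is solved by cyclic coordinate descent with:

* **sequential strong rules** — a predictor enters the working set only if
  its gradient at the previous $\lambda$ exceeds
  $v_j(2\lambda_k - \lambda_{k-1})$ — plus the ever-active set and warm
  starts;
* a **KKT repair sweep** that re-admits any violator before a solution is
  accepted, so the screening is safe;
* **unpenalized-block residualization**: penalized columns are projected
  against the unpenalized block in the $W$-inner product. The rotated
  intercept is nearly collinear with structure-loaded SNPs in admixed
  designs and this projection removes the resulting ill-conditioning. It
  provably changes neither the optimum nor the KKT system; the unpenalized
  coefficients are recovered in closed form;
* **loose-then-polish tolerances**: intermediate majorization iterations
  run coordinate descent at $100\times$ the final tolerance; the last pass
  runs strictly and finishes with an exact linear solve on the active set
  (kept only when coefficient signs are preserved), which brings the KKT
  residuals to machine precision;
* $\lambda \ge \lambda_{\max}$ stores the unpenalized-only solution by
  construction.

At the fixed point of the outer majorization loop the surrogate gradient
equals the true likelihood gradient $X^\top(y-\mu)$, so the bound changes
the *iteration*, not the *solution*: with $\hat\tau = 0$ the path is
exactly the logistic lasso (cross-checked against `glmnet` to $10^{-5}$),
and for the Gaussian family the solver is exact in one pass (cross-checked
against a dense-algebra oracle to $10^{-6}$). The general binomial path is
validated against an independent accelerated proximal-gradient minimizer
of the unprofiled objective.

Points deep in the overfitting region (near-saturated probabilities) may
exhaust the outer iteration budget; they are flagged `converged = FALSE`
with a warning rather than silently reported.

# Model selection and prediction

Two selectors are provided (`select_lambda`): training AIC
($-2\ell_{PQL} + 2\,\mathrm{df}$, df counting all nonzero fixed effects,
ties broken toward the sparser model) and validation AUC of mixed-model
predictions on a held-out set. For held-out splitting in related cohorts,
`split_families` partitions *connected components* of the relatedness graph
(GRM entries above 0.0884, twice the third-degree kinship coefficient)
atomically, so no family straddles the train/validation boundary.

Prediction for new individuals (`predict_mixed`) adds the kinship BLUP to
the fixed effects:

$$\hat\eta_s = X_s^\top \hat\beta + \hat\tau_1 V_{12}
 (cI + \hat\tau_1 V_1)^{-1}(\tilde Y_b - X\hat\beta),$$

which reuses the path's spectral decomposition
(per-component shrinkage $\hat\tau_1/(c + d_i)$) and reproduces the fitted
training linear predictor exactly when applied to the training set.
In the training eigenbasis this is GLS with a per-component ridge penalty
$1/(\hat\tau_1\Lambda_i)$ — the classical BLUP-as-ridge identity — whereas
the PC-GLM alternative (`predict_pc_glm`) keeps the first $r$ components
unshrunk and discards the rest.

# The simulation design

`simulate_bnpsd` draws structured genotypes from the Balding–Nichols /
admixture model: ancestral frequencies $p \sim U(0.01, 0.5)$,
subpopulation frequencies
$\mathrm{Beta}\big(p\tfrac{1-F_u}{F_u}, (1-p)\tfrac{1-F_u}{F_u}\big)$ with
drift $F_u$ linearly spaced in $[0.05, 0.2]$, and admixture proportions
either from Gaussian kernels on a 1D geography (`admix_1d`, $K$
subpopulations, kernel width 1) or as $K$ disjoint blocks (`independent`).
SNPs below 1% sample MAF are redrawn. `simulate_phenotype` builds the
liability

$$\operatorname{logit}(\pi_i) = \operatorname{logit}(\pi_0)
 - \log(1.3)\,\mathrm{Sex}_i + \log(1.05)\,\mathrm{Age}_i/10
 + \textstyle\sum_{j \in S}\beta_j \tilde g_{ij} + b_i,$$

with $\beta_j \sim N(0, h_g^2\sigma^2/|S|)$ on standardized dosages,
$b = U\delta$, $\delta \sim N(0, h_b^2\sigma^2 D)$ drawn along the
eigenvectors of the *kinship-panel* GRM (so the confounder is aligned with
the observable structure), and
$\sigma^2 = (\pi^2/3)/(1 - h_g^2 - h_b^2)$ anchoring the logistic residual
variance as the non-genetic share. Defaults (`sim_config()`) are the
package's reference study conditions — $n = 2500$, $p = 5000$ candidates,
50 000 panel SNPs, 1% causal, $K = 10$, $h_g^2 = 0.5$, $h_b^2 = 0.4$,
$\pi_0 = 0.1$ — and are not tuned per experiment; scaled-down runs pass
smaller sizes explicitly.

What the generator emulates: allele-frequency drift, admixture clines,
confounding of polygenic signal with structure, covariate effects, rare-SNP
filtering. What it does not: linkage disequilibrium within subpopulations
(SNPs are conditionally independent given ancestry), genotyping error,
missingness, case-control ascertainment, or X-chromosome dosage.

# Numerical choices at a glance

| choice | value | note |
|---|---|---|
| curvature bound $c$ | 4 | $\mu(1-\mu) \le 1/4$ |
| AI-REML tolerance / iterations | $10^{-5}$ / 100 | plus score check at the returned state |
| $\tau$ clamp | $10^{-6}\operatorname{Var}(\tilde Y)$ | boundary score one-sided |
| CD tolerance | $10^{-7}$ (final), $\times 100$ intermediate | exact active-set polish after |
| outer (majorization) tolerance | $10^{-6}$, 50 iterations | non-convergence flagged |
| $\lambda$ grid | 100 points, ratio 0.01 | log-spaced; $\lambda_{\max}$ from gradient at null fit |
| strong rule | sequential, $v_j(2\lambda_k - \lambda_{k-1})$ | ever-active kept; KKT repair |
| relatedness threshold | 0.0884 | `split_families` |
| GRM MAF filter | 0.01 | `estimate_grm` |
| AUC | Mann–Whitney, average ranks | ties get half credit |

# Limitations

* Binomial and Gaussian families only; a single kinship component is
  supported in prediction.
* $\hat\tau$ is a PQL quantity: attenuated for Bernoulli data, so it
  should not be read as a liability-scale heritability.
* The eigendecomposition is dense, $O(n^3)$: practical to a few thousand
  samples per fit on one core, which is the regime the package's own
  experiments use.
* Deep-overfitting path points may be flagged unconverged; selection
  criteria (AIC, validation AUC) never choose them in practice, but
  downstream code should check `converged`.
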