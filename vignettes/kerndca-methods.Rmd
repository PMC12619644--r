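---
title: "Kernel-based differential co-expression analysis: models, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-based differential co-expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kerndca)
```

## The problem

Differential co-expression analysis (DCA) asks whether the *correlation
structure* of a gene pathway — not the mean expression of its genes —
depends on a risk factor such as a mutation, an exposure, or age. A pathway
that is co-regulated under normal conditions can lose that coordination
under a risk factor, and such dysregulation is invisible to differential
(mean) expression analysis. Methods that test each gene pair separately pay
a multiple-testing price and cannot handle continuous or multivariate risk
factors; the classical eigengene approach summarizes the pathway by its top
principal component and misses signal carried by lower-variance components.

`kerndca` tests a whole pathway at once against one or several general
(continuous, discrete, or categorical) risk factors, while adjusting for
covariates, batch variables, and — critically — variance effects of the
risk factor itself.

## Model and procedure

Write $Y_{jk}$ for the (approximately normal) expression of gene
$k = 1, \dots, r$ in sample $j = 1, \dots, n$, $X$ for the risk factor(s),
$C$ for covariates, and $M$ for batch variables.

1. **Residualization.** Each gene is regressed on $[1, X, C, M]$ by least
   squares; the conditional variance $s_{jk}^2$ is estimated either within
   risk-factor groups (categorical $X$) or by a double GLM (continuous or
   discrete $X$): a mean regression with inverse-variance weights
   alternating with a gamma log-link regression of squared residuals on the
   variance covariates. Standardized residuals are
   $\tilde e_{jk} = e_{jk} / s_{jk}$. Standardization is what prevents a
   risk factor with *variance-only* effects from masquerading as
   differential co-expression.
2. **Individual-specific gene correlations (IGC).** For each of the
   $q = r(r-1)/2$ gene pairs, the per-sample product
   $Z_{ji} = \tilde e_{jk(i)} \tilde e_{jk'(i)}$ estimates that pair's
   correlation for sample $j$. Under the null hypothesis, every column of
   $Z$ is independent of $X$.
3. **Kernel trace statistic.** With a similarity matrix $K_Z$ for the rows
   of (column-centered) $Z$ and a linear kernel
   $K_X = X_c X_c^\top$ on the centered, unit-variance-scaled risk-factor
   columns, the Hilbert–Schmidt independence criterion statistic is
   $T = \operatorname{tr}(K_Z K_X) / n$. Three kernels are computed:
   linear ($Z Z^\top$), projection ($U U^\top$ over the retained left
   singular vectors of $Z$), and Gaussian (radial basis,
   $\exp\{-\nu \lVert Z_{j\cdot} - Z_{j'\cdot}\rVert^2\}$).
4. **Permutation null.** For each of $B$ permutations, a null expression
   matrix is rebuilt as
   $Y^{(b)}_{jk} = \hat\mu_{jk} + s_{jk} \tilde e_{\pi_b(j), k}$ — the same
   row permutation for every gene, so gene–gene correlations are preserved
   while the association with $X$ is broken, and the mean and variance
   structure of the original fit is carried over. The complete estimation
   pipeline (mean fit, variance fit, standardization, cross products,
   kernels) is re-run on $Y^{(b)}$; the empirical p-value is
   $p = (\#\{T^{(b)} \ge T\} + 1)/(B + 1)$.
5. **Kernel combination.** Per-kernel empirical p-values are combined with
   Fisher's statistic $T' = -2 \sum_d \log p_d$, whose null distribution is
   built from the same permutation stream (within permutation $b$, each
   kernel's statistic is ranked against its own null, self-inclusively, so
   $p_d(b) \ge 1/B$). Because the combined statistic is itself calibrated
   empirically, the procedure is valid under arbitrary dependence between
   kernels.

The eigengene baseline tests $n R^2$ of the top left singular vector of
centered $Z$ on the risk-factor columns, under the identical permutation
scheme, so comparisons against it differ only in the statistic.

## Why the full pipeline is re-run inside each permutation

The observed statistic is a function of *estimated* mean and variance
coefficients. If permutations reused the original fits, the null statistics
would be drawn from a different (narrower) distribution than the observed
one — the same mechanism that breaks moment-matching approximations whose
assumptions require the two kernels to be unaffected by the adjustment.
Re-estimating everything inside each permutation makes the null
distribution match the sampling pipeline exactly. A `refit = "recycle"`
option reuses the observed conditional standard deviations for speed
comparisons; it is not the default.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `B` | 1000 | permutations; the attainable p-value floor is $1/(B+1)$. Testing $R$ pathways at level $\alpha$ needs at least $R/\alpha$ |
| `nu` | $10^{-4}$ | Gaussian kernel bandwidth, fixed (no data-adaptive heuristic), on the scale of squared distances between cross-product rows |
| `proj_tol` | $10^{-8}$ | relative singular-value cutoff defining the projection kernel's rank |
| `variance` | `"auto"` | `"groupwise"` when all risk factors are categorical, else `"dglm"`; `"constant"` disables variance adjustment |
| `max_iter`, `tol` | 25, $10^{-6}$ | double-GLM outer iterations and relative gamma-deviance tolerance (initialized at the homoscedastic fit) |
| `min_size` | 5 | smallest pathway size retained from a GMT file |

Group-wise variances use the unbiased $n_g - 1$ denominator; the double
GLM's gamma fit carries no small-sample correction — any residual bias is
absorbed by the permutation null, which applies the identical estimator.

## The Gaussian kernel form

Two forms are implemented. The default is the radial basis function on the
squared Euclidean distance between cross-product rows. A variant that
squares the *inner product* instead,
$\exp\{-\nu (Z_{j\cdot} Z_{j'\cdot}^\top)^2\}$, is available via
`gaussian_form = "inner-product"`. The inner-product form is not positive
semidefinite, and its trace statistic against a centered risk-factor kernel
can be shown to *decrease* under differential co-expression (to first order
in $\nu$ it equals $-\nu\, x_c^\top (G \circ G)\, x_c / n \le 0$ with
$G = Z Z^\top$), so under the one-sided permutation test it has essentially
no power while remaining correctly calibrated under the null. The RBF form
is therefore the default; the variant is retained for methodological
comparison.

## Design choices where the design was open

- **Centering and scaling.** Cross-product columns are mean-centered and
  risk-factor columns are centered and scaled to unit population variance
  before kernel construction. Centering one side makes the trace statistic
  equal the standard HSIC numerator for linear kernels; scaling makes $T$
  comparable across risk-factor encodings. Validity is unaffected because
  the permutation null applies the identical transformation.
- **Per-permutation Fisher p-values** use the self-inclusive rank
  $p_d(b) = \#\{b': T_d(b') \ge T_d(b)\}/B$, keeping every logarithm
  finite. Ties count as exceedances everywhere.
- **Permutation stream.** All $B$ permutation index vectors are drawn up
  front from the master seed, so results are reproducible and independent
  of execution order; per-pathway sub-seeds in `run_study()` are derived by
  hashing the master seed with the pathway name, so editing the pathway
  collection never changes another pathway's p-value.
- **Eigengene statistic.** $n R^2$ of the top left singular vector on the
  risk factors; equivalent to testing the top eigenvector of the linear
  kernel matrix.
- **Degenerate inputs.** Rank-deficient designs name their collinear
  columns; groups with fewer than two samples, zero within-group variances,
  and constant risk factors are explicit errors. A permutation whose
  variance refit fails is redrawn once; a second failure aborts with
  diagnostics.
- **Double-GLM variance covariates** default to the risk factor(s) only;
  other columns can be added (`variance_covariates`), since variance
  effects of covariates or batches can also be modeled.

## The simulators

`simulate_mvn_pathway()` draws each sample's expression vector from a
multivariate normal with sample-specific structure: means
$\alpha_k + X_j + C_j$, log variances $1 + \delta_k X_j$ with
$\delta_k \sim U(0, \delta')$, and pairwise correlations
$\rho_j + \tau_{\text{signed}} X_j$ with per-sample baseline
$\rho_j \sim U(0.25, 0.50)$ and effect $\tau \sim U(0.1, 0.2)$ (zero for
null pairs; a pair carries the effect only when both genes are non-null).
The interpretation of the pairwise term as a *correlation* (converted to a
covariance through the per-gene conditional SDs) follows from its
$U(0.25, 0.50)$ baseline scale. Under the mixed-sign scheme the
per-sample correlation matrix can lose positive semidefiniteness and is
repaired by eigenvalue clipping at $10^{-8}$ plus rescaling to unit
diagonal; clipping never occurs in the positive scheme, and clip events
are counted in the output.

`simulate_nb_counts()` draws negative-binomial counts (dispersion 0.25,
variance $\mu + 0.25\mu^2$) with log means
$\log \alpha_k + \beta_k X_j + \gamma_k C_j + \delta_k X_j U_{jk}$, where
the latent factor $U_{jk}$ is independent across genes — so pathways built
from these genes satisfy the DCA null, yet the interaction induces a
risk-factor variance effect once counts are log-transformed. Baseline
sizes are $\alpha_k \sim \text{Lognormal}(5.54, 0.697)$ (typical counts
near $e^{5.54} \approx 255$), effect sizes
$\beta_k, \gamma_k \sim N(0, 0.1^2)$ and $\delta_k \sim N(0, 0.025^2)$.
Samples are rescaled to library sizes of $2 \times 10^6$ or $10^7$ by
multinomial resampling, which preserves integer counts and NB-like
marginals. The analysis route for counts is `transform_counts()`
($\log_2(\text{count} + 2)$ plus a log-library-size covariate) followed by
double-GLM adjustment.

What the generators deliberately do not emulate: latent batch structure
correlated with the risk factor, gene-length or GC composition effects,
zero inflation, and outlying samples. Passing tests on these simulations
therefore demonstrates calibration and power under the stated models, not
robustness to unmodeled confounding — unmeasured batch effects associated
with the risk factor remain a real hazard in applications and must be
supplied through `M` when known.

## Problem sizes used in the test suite

The packaged experiments are scaled-down replications chosen to exercise
the study conditions (n = 300, r = 10 pathways) at Monte-Carlo sizes a
test suite can afford: type-I experiments use 150–200 pathways with
B = 300–400 permutations and two-binomial-SE bounds at those counts;
power comparisons use 200 replicates at B = 300. The packaged
reproduction script runs 200 pathways per setting with B = 500. Larger runs sharpen the
Monte-Carlo bounds but do not change the procedures.

## Known limitations

- Permutation cost grows as $n^2$ per kernel evaluation and linearly in
  $B$; biobank-scale data should use the moment-matched Gamma mode
  (`mode = "asymptotic"`, guarded below $n = 1000$), which assumes the
  large-sample null of the trace statistic.
- The double GLM requires the variance model to be correctly specified in
  its covariates; a misspecified variance model can leak variance effects
  into the test. Rank-based transformations of expression are discouraged
  for the same reason: they induce variance and covariance effects.
- Gene identifiers are matched as exact strings; no alias resolution.
- Pathways smaller than 2 matched genes cannot be tested and are skipped.
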