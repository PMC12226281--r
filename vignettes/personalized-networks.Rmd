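---
title: "Personalized gene networks with a sample-specific GIC: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized gene networks with a sample-specific GIC: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Ordinary gene-network estimation regresses each target gene on the remaining
genes and reports one coefficient vector for the whole cohort. That averages
away exactly what personalized analyses are after: regulatory interactions
whose strength depends on a continuous sample characteristic — a drug
sensitivity Z-score, disease progression, survival — which we call the
*modulator* $m$. `netgic` estimates, for every target gene $\ell$ and every
*target sample* $\alpha$, a sample-specific coefficient vector
$\beta_{\ell\alpha} = \beta_\ell(m_\alpha)$, so that the inferred network
(nonzero coefficients are directed regulator-to-target edges) varies along
the modulator axis.

# Model and estimator

## Kernel-weighted elastic net

The varying-coefficient model $y_{i\ell} = r_i^\top \beta_\ell(m_\alpha) +
\varepsilon_{i\ell}$ is fitted locally: samples are weighted by a Gaussian
kernel in modulator distance,
$$k_{i\alpha} = \exp\{-(m_i - m_\alpha)^2 / h\},$$
and the estimate solves
$$\hat\beta_{\ell\alpha} = \arg\min_\beta\; \tfrac12 \sum_i k_{i\alpha}
 (y_{i\ell} - r_i^\top\beta)^2
 + \lambda \sum_j \{\tfrac12 (1-\pi)\beta_j^2 + \pi |\beta_j|\}.$$
The bandwidth $h$ (in squared modulator units) controls locality; $\lambda$
the overall shrinkage; $\pi \in [0,1]$ the ridge/lasso mix. There is no
intercept: all expression columns are mean-centered (and by default
unit-scaled) at ingestion, and coefficients are reported back on the
original scale.

Absorbing the kernel into the data — each row of $(y, R)$ scaled by
$\sqrt{k_{i\alpha}}$ — turns this into an ordinary elastic net on the
*weighted design* $(y^*, R^*)$. `build_weighted_design()` performs exactly
that transformation, and the identity
$(y^*-R^*\beta)^\top(y^*-R^*\beta) = \sum_i w_i (y_i - r_i^\top\beta)^2$
is asserted by a property test. With this convention the transformed
response has variance $\mathrm{Var}(y^*_i) = w_i\sigma^2$, which is the
per-sample variance the criterion below uses. Two practical regularizations
are applied to the raw kernel weights:

* samples with raw weight below $10^{-8}$ are dropped from the local fit
  (they carry no information and would only destabilize the likelihood);
* the retained weights are rescaled to sum to the retained count $n'$, so
  the likelihood magnitude stays comparable when the bandwidth changes.

The solver is cyclic coordinate descent on the Gram form with covariance
updates, warm starts along a descending $\lambda$ path, sequential
strong-rule screening, and an active-set strategy — the standard design for
penalized linear models. Tolerance is $10^{-7}$ on the maximum coefficient
change, with up to $10^5$ sweeps for a direct fit. During grid search each
path point is allowed 500 sweeps; the selected point is re-solved to full
tolerance if it hit that cap. A second, independent solver
(`fit_by_lqa()`) iterates ridge-type systems from the local quadratic
approximation (LQA) of the L1 penalty, with curvature
$P'(|\beta_j^0|)/|\beta_j^0|$ and a $10^{-6}$ drop threshold; the two
solvers agreeing within $10^{-4}$ is part of the test suite.

## The sample-specific GIC

Because the estimator is penalized and kernel-weighted — not maximum
likelihood — AIC-type theory does not apply directly. The generalized
information criterion used here corrects the log-likelihood with an
influence-function bias term computed from the LQA of the penalty:
$$\mathrm{GIC} = -2\sum_i \log f(y^*_i \mid r^*_i, \hat\beta)
 + 2\,\mathrm{tr}\{R(\hat G)^{-1} Q(\hat G)\},$$
with, restricted to the active set $A$,
$$R(\hat G) = \tfrac{1}{n'} R^{*\top}_A R^*_A + \Sigma_\lambda,\qquad
 Q(\hat G) = \tfrac{1}{n'}\{R^{*\top}_A \hat\Lambda^2 R^*_A
 - \Sigma_\lambda\hat\beta_A \mathbf{1}^\top \hat\Lambda R^*_A\},$$
$\hat\Lambda = \mathrm{diag}\{(y^*_i - r^{*\top}_i\hat\beta)/\sigma^{*2}_i\}$,
$\sigma^{*2}_i = w_i\hat\sigma^2$, and
$\Sigma_\lambda = \mathrm{diag}\{\lambda[(1-\pi) + \pi/|\hat\beta_j|]\}$.
The density $f$ is Gaussian with the same per-sample variances. Zero
coefficients are excluded from the matrices (their LQA curvature is
undefined; the LQA argument itself fixes them at zero). In the unweighted,
vanishing-penalty limit the bias term reduces to the classical
variance-sandwich trace and concentrates near $|A| + 1$, which is verified
by a Monte Carlo test.

Three points in this formula are genuinely underdetermined, and the package
takes an explicit position on each:

* **The variance estimator.** $\hat\sigma^2$ is never defined by the
  criterion itself. The package defaults to the maximum-likelihood form
  $\hat\sigma^2 = RSS^*/n'$; the degrees-of-freedom-adjusted
  $RSS^*/(n'-|A|)$ is available via `estimate_noise_scale(method =
  "unbiased")`. The MLE form is what glmnet-based pipelines compute, and in
  the simulation benchmark it is the choice that reproduces the reference
  selection behavior; the adjusted form weakens the bias correction and
  noticeably over-selects.
* **The scale of $\Sigma_\lambda$.** As written above, $\Sigma_\lambda$
  enters $R(\hat G)$ un-normalized next to a Gram matrix divided by $n'$.
  For moderate $\lambda$ the penalty curvature then dominates and shrinks
  the bias term; a defensible alternative derivation scales
  $\Sigma_\lambda$ by $1/n'$ in both matrices. The default keeps the
  un-normalized form; `gic_scale_penalty = TRUE` in the selection routines
  switches to the scaled reading, which selects markedly sparser models.
  Under strong signals the scaled form is closer to the reference benchmark,
  under weak signals the un-normalized form is; neither dominates, so the
  printed form wins as default.
* **The density's variance structure.** The heteroskedastic per-sample
  variances $w_i\hat\sigma^2$ follow from the design transformation and are
  the default; a homoskedastic variant exists internally and performs far
  worse (it removes the term that makes likelihoods comparable across
  bandwidths).

## Comparator criteria and cross-validation

AIC, AICc, BIC, HQC, EBIC (default $\gamma = 0.5$) and BIC-p
($-2\ell + df(\log n' + 2\log p)$) are computed from the *homoskedastic
Gaussian MLE log-likelihood* of the weighted fit
($\hat\sigma^2 = RSS^*/n'$), with $df$ the number of nonzero coefficients —
i.e. exactly what generic information-criterion post-processing of a
penalized linear fit computes. Feeding them the GIC's heteroskedastic
likelihood instead would change their selection behavior qualitatively
(AIC would stop over-selecting, which contradicts its known behavior in
this setting). K-fold CV (default $k = 10$, seeded folds drawn on the
retained samples) scores each fold by the kernel-weighted squared
prediction error normalized by the fold's weight mass; fold fits use a
$10^{-4}$ coefficient tolerance, which leaves the error curves unchanged at
the resolution the selection needs while cutting its cost substantially.

## Hyperparameter search

`select_hyperparameters()` evaluates the full grid exhaustively per
(target gene, target sample). Defaults: 50 $\lambda$ values log-spaced from
$\lambda_{\max} = \max_j |R^{*\top}y^*|_j / \max(\pi, 10^{-3})$ (the exact
full-shrinkage point of the objective above) down to $10^{-3}\lambda_{\max}$,
recomputed per $(\pi, h)$; $\pi \in \{0.1, 0.3, 0.5, 0.7, 0.9, 1.0\}$; and
8 bandwidths log-spaced over $[0.05, 2] \times \mathrm{sd}(m)$. Ties are
broken toward larger $\lambda$, then larger $h$, then larger $\pi$ (the
least complex model). Warm starts are used only along the $\lambda$ path,
so results do not depend on the order in which bandwidths are visited.
Every stochastic step (CV folds, simulation draws) takes an explicit seed;
identical inputs and seed give bit-identical results.

# Simulation framework

The generator emulates a varying-coefficient benchmark: $n = 300$ samples,
modulators $m_i \sim U(-1, 1)$; $p = n_{\text{genes}} - 1$ regulators with
AR(1) correlation $\rho^{|j-k|}$, $\rho = 0.5$; a random 10% of regulators
carry signal; per signal column, coefficients for 95% of samples are drawn
from a scenario-specific uniform range (Scenario 1: $U(0.1,1)$; 2:
$U(0.9,1)$; 3: $U(-1,-0.1)$; 4: $U(-1,-0.9)$), sorted against the modulator
(descending for type 1, ascending for type 2) so the edge weight varies
smoothly and monotonically with the modulator; the 5% of samples with the
largest modulator values get all-zero coefficients (the placement is not
dictated by the benchmark's description; putting the zeros at the top of
the modulator range makes the coefficient curves continue their trend into
extinction, and is flagged as a modeling choice). Targets follow
$y_i = r_i^\top \beta(m_i) + \varepsilon_i$, $\varepsilon_i \sim N(0,1)$.
Signal columns are redrawn each iteration (seeded).

`run_benchmark()` generates data, runs the full grid selection for each of
40 randomly chosen target samples under each requested criterion (fits are
shared; each criterion picks its own minimizer), and pools true-positive
and true-negative rates over all (regulator, target sample, iteration)
entries. Weight-estimation error is
$\mathrm{MAE} = \omega^{-1}\sum_\alpha \sum_j
|\beta_{j\alpha} - \hat\beta_{j\alpha}|$ (summed, not averaged, over
regulators — the convention of the benchmark it mirrors) and prediction
error is the mean squared residual at the target samples.

The default scale used by the package's own acceptance checks is 20
iterations per cell (reported rates stabilize to about $\pm 0.02$ at that
depth); the full study design uses 100. A 50-gene cell with four criteria
takes roughly 6 minutes on one core, a 100-gene cell about 7.

What the generator does *not* emulate — and hence what passing benchmarks
do not certify about real expression data: heavy-tailed or batch-structured
noise, measurement error in the modulator, non-monotone coefficient curves,
correlated signal columns beyond AR(1), and missingness. The
varying-coefficient curves are monotone step-interpolations by
construction, so bandwidth selection is only ever tested against smooth,
single-regime alternatives plus one sharp extinction at the modulator's
upper end.

# Downstream network operations

For condition-level summaries the package implements the pipeline used in
drug-sensitivity analyses: per-edge medians over a group of target samples
(`aggregate_group_median`), a consensus across conditions keeping only
edges nonzero in *every* condition with their mean weight
(`consensus_mean`), and top-fraction filtering by absolute weight
(`top_fraction_edges`; ties at the cutoff are all retained rather than
silently dropped). A multi-drug sensitivity *module* is the first principal
component of the column-centered sensitivity matrix, sign-fixed so the
largest-magnitude loading is positive (`drug_sensitivity_module`). The
*regulate-effect change* of an edge is the range (max minus min) of its
coefficient across target samples — "range" being the package's
interpretation of an effect-change summary that is described only verbally
in the source analyses — and per-regulator totals sum these ranges over
target genes (`regulate_effect_change`).

# Numerical and degenerate-input policy

* Near-singular $R(\hat G)$: a $10^{-10}$ ridge jitter is added (with a
  warning) before inversion.
* Empty active set with $\lambda > 0$: the GIC is $-2\ell$ with zero bias.
* Fits with no residual degrees of freedom, or exact interpolation, raise
  degenerate-fit errors; grid points that fail are skipped and recorded,
  and selection fails only if every point is degenerate.
* Per-(gene, sample) failures in whole-network fitting are collected in
  the result's `failures` list rather than aborting the remaining fits.
* All criteria treat non-finite values as $+\infty$ during selection.

# Known limitations

The three GIC ambiguities above are resolved by measurement against a
single benchmark family; other data regimes might prefer the alternative
readings, which is why they remain switchable. The package handles one
continuous modulator; categorical or multivariate sample characteristics
are out of scope. The exhaustive grid is embarrassingly parallel but runs
single-threaded here.
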