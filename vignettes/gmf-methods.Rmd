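---
title: "Generalized matrix factorization with gmfab: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized matrix factorization with gmfab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmfab)
```

## The model

`gmfab` fits generalized matrix factorization (GMF) models to an
$n \times m$ response matrix $Y$ — cells by genes in the single-cell
setting, but any exponential-dispersion-family matrix works. Each entry is
modeled as

$$y_{ij} \sim \mathrm{EF}(\theta_{ij}, \phi), \qquad
  g(\mu_{ij}) = \eta_{ij}
  = x_{i:}^\top \beta_{:j} + \gamma_{i:}^\top z_{:j}
  + u_{i:}^\top v_{:j},$$

with a family-specific variance function $\nu(\mu)$, dispersion
$a_{ij}(\phi) = \phi / w_{ij}$ for user weights $w_{ij} > 0$, and a smooth
bijective link $g$. The linear predictor combines three parts:

* a **column-specific regression effect** $X B^\top$ — row covariates such
  as batch indicators, with one coefficient vector per gene. With an
  intercept column in $X$, $\beta_{0j}$ is a gene baseline;
* a **row-specific regression effect** $\Gamma Z^\top$ — gene covariates
  with one coefficient vector per cell. With an intercept column in $Z$,
  $\gamma_{0i}$ is an estimated cell scale factor, which lets the model
  run on raw counts: the library size is treated as an unknown to
  estimate rather than a fixed offset (a fixed offset is still supported
  through the `offset` argument of `gmfData()` and is excluded from all
  penalties and updates);
* a **latent factorization** $U V^\top$ of rank $d$, the "meta-gene"
  scores and gene loadings that carry the biological signal of interest.

Supported families (`gmfFamily()`): Gaussian, Poisson, binomial, gamma,
negative binomial (NB2 variance $\mu + \mu^2/\mathrm{size}$) and
quasi-Poisson. Links: identity, log, logit, sqrt, inverse; the default is
the family's canonical choice, with log as the conventional choice for the
negative binomial. The Gaussian, gamma and quasi-Poisson dispersions are
estimated by Pearson moments; Poisson and binomial have $\phi = 1$; the
negative-binomial size can be fixed or re-estimated once per epoch by
method of moments (the estimate is frozen within each epoch).

## Penalized quasi-likelihood

Rather than integrating the latent factors out (which scales poorly), the
factors are treated as fixed parameters and the penalized negative
log-likelihood

$$\ell_\lambda(\psi) = -\sum_{(i,j) \in \Omega} \log f(y_{ij};
  \theta_{ij}, \phi) + \frac{\lambda}{2} \lVert U \rVert_F^2
  + \frac{\lambda}{2} \lVert V \rVert_F^2$$

is minimized, where $\Omega$ is the set of observed entries. The ridge
penalty stabilizes the non-convex problem and shrinks the singular values
of $U V^\top$, favoring compact low-rank representations. The
response-only constant $c(y, \phi)$ is included in the objective, so
information criteria computed from it live on the standard likelihood
scale. For the quasi-Poisson family the "log-likelihood" is the Poisson
kernel scaled by $1/\phi$; its absolute level is a quasi-likelihood
convention and only differences should be interpreted.

All derivatives flow through two per-entry kernels with respect to
$\eta$, stored with the sign of the *negative* log-likelihood so that
descent directions are unambiguous:

$$\dot D = -\frac{w (y - \mu)}{\phi\, \nu(\mu)\, \dot g(\mu)}, \qquad
  \ddot D = \frac{w\, \alpha(\mu)}{\phi\, \nu(\mu)\, \dot g(\mu)^2},
  \qquad \alpha(\mu) = 1 + (y - \mu) \left\{ \frac{\dot\nu(\mu)}{\nu(\mu)}
  + \frac{\ddot g(\mu)}{\dot g(\mu)} \right\}.$$

Setting $\alpha \equiv 1$ gives the expected (Fisher) curvature, which is
strictly positive and is the default preconditioner. Every analytic
gradient in the package is validated against central finite differences
of the objective in the test suite; this contract, not a transcription
convention, fixes all signs.

## Identifiability

The decomposition is made unique by (`projectConstraints()`):

* orthogonality to the covariate column spaces,
  $X^\top \Gamma = 0$, $X^\top U = 0$, $Z^\top V = 0$ — enforced by
  absorbing the overlapping components into the regression blocks by
  least squares, which leaves $\eta$ unchanged;
* one of three rotation/scale/sign normalizations:
  **B1** (default; the PCA convention used throughout the RNA-seq
  literature): $V$ orthonormal, $U^\top U$ diagonal with decreasing
  entries, first non-zero entry of each $V$ column positive;
  **B2**: the mirror image; **B3** (the factor-analysis convention):
  unit-variance centered factor columns and lower-triangular $V$ with
  positive diagonal, which requires an intercept in $X$.

The rotation is computed from thin QR factorizations of $U$ and $V$
followed by an SVD of the small $d \times d$ core, so the singular values
of $U V^\top$ are preserved exactly. Degenerate (tied) singular values
leave the rotation within the tied block fixed only by the sign rule;
"first non-zero" uses a $10^{-12}$ threshold with ties broken by the
lowest row index. Every fitter optimizes in the unconstrained
parametrization and projects once at the end; the reported `objective` is
the value reached by the optimizer, since the B1 normalization
redistributes scale between $U$ and $V$ and thereby changes the penalty
term (the data misfit is invariant).

## The three estimation algorithms

**AIRWLS** (`fitAIRWLS`) alternates Fisher scoring across the column
problems — each $(\beta_{:j}, v_{j:})$ against the design $[X, U]$ — and
the row problems — each $(\gamma_{i:}, u_{i:})$ against $[Z, V]$ — with
the ridge applied to the latent coordinates only. All problems on one
side share their design matrix, so the per-problem normal matrices are
assembled with a single large matrix product and only tiny
$K \times K$ solves remain in the loop. A global step-halving safeguard
(starting at $\rho = 1$, at most 10 halvings) keeps the objective
monotone.

**Diagonal quasi-Newton** (`fitNewton`) updates all blocks at once with
elementwise steps $-\rho\, G / H$, where $H$ is the diagonal expected
curvature ($H_U = \ddot D (V * V) + \lambda$, etc.). The default damping
$\rho = 0.1$ with step halving trades speed for robustness; on
well-behaved problems $\rho$ up to 1 is safe and much faster.

**Adaptive SGD** (`fitSGD`) is the scalable option. Rows and columns are
split into balanced chunks (`minibatchPartition()`; chunk sizes default
to about $\min(n, 1000) \times \min(m, 250)$); each inner iteration
visits one block $B = I \times J$, computes inflated, unbiased
minibatch derivatives

$$\hat G_{U,I} = (m / m^*_J)\, \dot D_B V_J + \lambda U_I, \qquad
  \hat G_{V,J} = (n / n^*_I)\, \dot D_B^\top U_I + \lambda V_J$$

(and their curvature analogues), refreshes exponential moving averages
$\bar G \leftarrow (1 - \alpha_1) \bar G + \alpha_1 \hat G$,
$\bar H \leftarrow (1 - \alpha_2) \bar H + \alpha_2 \hat H$ on the
visited rows, and applies the partial update
$U_I \mathrel{+}= \rho_t \Delta_I$ with
$\Delta_I = -\alpha_t \bar G_I / \bar H_I$, learning rate
$\rho_t = k_0 / (1 + k_0 k_1 t)^\tau$ and bias factor
$\alpha_t = (1 - \alpha_2^t) / (1 - \alpha_1^t)$ (defined as 1 when
$\alpha_1 = \alpha_2$). Column chunks are swept in order; the row chunk
of each block is drawn by cycling without replacement through a reshuffled
queue, so every epoch covers all columns and row coverage is balanced
across epochs. The covariate rows $B_J$ and $\Gamma_I$ are updated with
the same adaptive rule (with zero penalty) alongside the latent blocks
they share entries with.

Two numerical notes on the adaptive step. First, with zero-initialized
accumulators the ratio $\bar G / \bar H \approx (\alpha_1/\alpha_2)
(\hat G / \hat H)$ in early iterations, i.e. the first steps are
amplified by about $\alpha_1/\alpha_2 = 10$ at the default smoothing
coefficients; the conservative default $k_0 = 0.01$ absorbs this, and
larger $k_0$ should be paired with either more balanced smoothing
coefficients or a warm curvature history. Second, $\bar H$ is floored at
$10^{-8}$ so the elementwise division never produces non-finite steps;
any non-finite update aborts with a diagnostic naming the block and
epoch.

Defaults follow the convention $\alpha_1 = 0.1$, $\alpha_2 = 0.01$,
$k_0 = k_1 = 0.01$, $\tau = 0.75$ ($\tau$ must lie in $(1/2, 1]$ so the
Robbins–Monro conditions hold).

**Convergence** is declared when the relative change of the monitored
objective stays below `tol` (default $10^{-5}$) for 3 consecutive epochs.
The deterministic fitters monitor the full objective (they compute it for
step control anyway); SGD monitors a fixed, seeded 10% subsample of the
observed entries, rescaled to the full-objective scale. An estimated
dispersion is refreshed once per epoch (SGD smooths it with weight
$\alpha_2$ on the monitoring subsample).

**Missing entries** are handled by model-based imputation: inside every
visited block, unobserved cells of the working response are replaced by
the current fitted means before differentiation, so $\dot D = 0$ there and
their stored values (which may be `NA`/`NaN`) are never read. The final
completion `imputeValues()` returns $g^{-1}(\hat\eta)$ at the masked
positions exactly.

**Determinism**: all randomness (partitions, monitoring subsample, chunk
cycling) derives from `control$seed`; identical data, configuration and
seed reproduce the returned fit bitwise. The partition is drawn with seed
`control$seed` itself, the monitoring subsample with `seed + 1` and the
chunk cycling with `seed + 2`.

## Initialization

`gmfInit()` implements a structured null-residual start: column GLMs for
$B$, row GLMs for $\Gamma$ given the column offsets, an SVD of the
deviance (default) or Pearson residuals of that regression-only fit —
masked cells set to 0, the null model's own prediction — and a final
round of column GLMs for $V$ with the factors as design. The left
singular vectors are scaled by their singular values, so $U$ carries the
magnitude and the start is consistent with the B1 normalization. Inner
GLMs run at most 50 IRLS iterations at tolerance $10^{-8}$; a
non-converged GLM falls back to least squares on a link-transformed
response for that fit (counted in the manifest). `method = "ols"`
replaces every GLM with that least-squares path — the transform is the
started log $\log(y + 0.5)$ for count families, an empirical logit for
the binomial — which is exact for the Gaussian-identity family and much
cheaper in high dimensions. The row/column fits are independent by
construction, so their results do not depend on execution order.

## Rank selection

Three routes are provided:

* **Information criteria** (`informationCriteria()`):
  $\mathrm{AIC} = 2\,\mathrm{nll} + 2k$,
  $\mathrm{BIC} = 2\,\mathrm{nll} + k \log |\Omega|$ with the full
  parameter count $k = pm + qn + d(n + m) + 1$. The count is not adjusted
  for the identifiability constraints; this is the conventional total for
  this model class and is echoed in the manifest.
* **Entrywise-holdout cross-validation** (`cvRankSelect()`): `folds`
  *independent* uniform holdouts (repeated holdout, not a disjoint
  K-fold; default fraction 0.3), each repaired so that every row and
  column keeps at least one training entry. For each fold the grid of
  ranks is fitted in ascending order with warm starts and scored on the
  held-out entries by the relative deviance and relative log-RMSE, both
  dimensionless ratios against the train-mean predictor and therefore
  averaged across folds per entry scale-free. Warm starts pad the
  previous rank's parameters with fresh columns drawn from
  $N(0, 10^{-4})$: exactly-zero padded columns would be a stationary
  point of every update rule (all gradients with respect to them vanish
  identically), so the natural "zero column" warm start is perturbed by
  this negligible seeded noise. Holdout entries are masked before
  initialization, so no information leaks.
* **Spectral rules** (`spectralRank()`): singular values of the
  *column-centered* residual matrix of the regression-only fit — i.e. the
  PCA spectrum of the null residuals. Centering matters: deviance
  residuals of count families are skewed, so their per-gene means are
  non-zero even at a perfect null fit, and the uncentered matrix carries
  an artifactual dominant component that is constant across cells (about
  three times the noise edge on structure-free data). The eigengap rule
  returns $\arg\max_{k \le d_{max}} (\sigma_k - \sigma_{k+1})$; the elbow
  rule returns the knee of the cumulative profile (maximum perpendicular
  distance to its chord).

## The synthetic-data generators

`simulateGMF()` draws from the exact model: Gaussian intercepts, latent
entries scaled so that `snr` equals the standard deviation of the latent
part of $\eta$, responses from the requested family. The returned truth
is projected to B1 so fitted and true parameters are directly
comparable. It backs the parameter-recovery and algorithm-agreement
tests.

`simulateScRNA()` emulates a droplet scRNA-seq design: five (by default)
cell types evenly allocated, three batches with dense per-gene log-scale
effects (SD 0.3, reference coded, exported as dummy covariates),
log-normal library sizes (SD 0.4 on the log scale), gene baselines
$N(1, 1)$ and negative-binomial counts with size 2. The type signal is an
explicit rank-`nTypes` factor model: cell $i$ sits at its type centroid
(scaled coordinate axes, scale 1.5) plus within-type latent spread
(SD 0.6, the continuous within-type expression programs seen in real
data), and each latent axis loads on a random 20% of genes with
$N(0, 0.5)$ weights. The within-type spread is what makes the latent
signal genuinely `nTypes`-dimensional: a pure group-mean signal over $c$
balanced types spans only $c - 1$ dimensions once the gene baselines
absorb the across-cell mean, so "five well-separated types" would
otherwise have true rank 4. These scales were fixed once, when the
generator was designed, by inspecting the centered residual PCA spectrum
of draws so that the nominal rank equals `nTypes` while the types stay
well separated; they are generator conventions, not estimates from any
dataset.

What the generator deliberately does not emulate: zero inflation beyond
what the negative binomial produces, lineage/trajectory structure,
gene–gene correlation beyond the low-rank signal, and ambient
contamination. Tests passing on these draws therefore demonstrate
correctness of the estimation machinery under the stated model class,
not robustness to every artifact of real single-cell data.

## Problem sizes used by the bundled checks

The test-suite and the acceptance script run the pipeline at sizes chosen
to exercise the asymptotic behavior while staying comfortable on a
laptop-class single core: derivative checks at $20 \times 10$, the SVD
limit at $60 \times 30$, algorithm agreement at $1000 \times 100$
(rank 3), out-of-sample reconstruction at $1000 \times 150$ with a 30%
holdout, and rank selection at $2000 \times 200$ over the grid 3–7 with
two repeated holdouts. Subspace recovery is tracked over
$n \in \{200, 500, 1000\}$ at fixed $m = 30$, $d = 3$.

## Known limitations

* The deterministic fitters materialize several $n \times m$ dense
  matrices per epoch; SGD's block updates avoid that, but this
  implementation stores $Y$ densely regardless, so matrices far beyond
  $10^6$ rows are out of its intended range.
* Per-column families, zero-inflated models and Tweedie variance
  functions are not supported; quasi-Poisson is the only
  beyond-likelihood variance model.
* The quasi-Newton and SGD preconditioners are diagonal; strongly
  correlated covariate columns slow them down (AIRWLS, which solves the
  full small systems, is the robust fallback).
* The per-epoch moment estimator of the negative-binomial size is biased
  upward when the factorization partially absorbs the overdispersion;
  it is an order-of-magnitude device, not an efficient estimator.
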