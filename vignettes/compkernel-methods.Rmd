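---
title: "Kernel methods for compositional data: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel methods for compositional data: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compkernel)
```

## The statistical problem

Microbiome profiles and other relative-abundance measurements are
*compositional*: a sample is a vector $x \in S^{p-1} = \{x \ge 0,\,
\sum_j x_j = 1\}$, only ratios between parts are meaningful, and the unit-sum
constraint couples every component to every other. Two consequences drive the
design of this package:

1. **Estimation.** Regression methods built for $\mathbb{R}^p$ can be applied
   to simplex-valued covariates, but their implicit geometry is wrong. We
   instead estimate the conditional mean $f^*(x) = E[Y \mid X = x]$ by kernel
   ridge regression with kernels *targeted at the simplex*, so that the
   hypothesis space respects the domain.
2. **Interpretation.** "Increase $x_j$, hold the rest fixed" is impossible on
   the simplex. Influence and dependence measures must move along the simplex,
   not off it.

## Estimator

For a kernel $k$ with RKHS $\mathcal{H}_k$, the penalized least-squares
estimate over $\mathcal{H}_k$ has, by the representer theorem, the dual form
$\hat f(\cdot) = \sum_{i=1}^n \hat\alpha_i k(X_i, \cdot)$, where
$\hat\alpha$ solves $(K + n\lambda I)\hat\alpha = y - \bar y$ with
$K_{ij} = k(X_i, X_j)$. The penalty multiplies $n$ so that a $\lambda$ grid
transfers across sample sizes. Regression centers $y$ and restores the mean as
an intercept; binary classification maps labels to $\pm 1$, fits the same
ridge system, and thresholds predictions at zero. Both are exposed through
`krr_fit()` / `predict()`.

## The kernel families

`kernel_spec()` supports nine families in four groups:

* **Euclidean restrictions** — `linear` ($\langle x, y\rangle$) and `rbf`
  ($\exp(-g\|x-y\|^2)$). Universal but geometry-agnostic baselines.
* **Aitchison geometry** — `aitchison` and `aitchison-rbf` operate on the
  shifted centered log-ratio
  $\mathrm{clr}_c(x) = \log \tilde x - \overline{\log \tilde x}$ with
  $\tilde x = (x + c)/\sum_j (x_j + c)$. The shift $c \ge 0$ makes the
  transform defined in the presence of zeros and is treated as a *tunable
  hyperparameter* of the kernel rather than a fixed pseudo-count chosen during
  preprocessing: zero-replacement choices are rarely biologically justified,
  so we let cross-validation pick $c$. The RKHS of the Aitchison kernel is the
  span of log-contrast functions $\beta^\top \log(x)$, $\sum_j \beta_j = 0$, so
  Aitchison-kernel ridge is exactly ridge-penalized log-contrast regression —
  an identity the test suite asserts to $10^{-6}$ against an explicit
  feature-map oracle.
* **Probability distances** — `prob-js`, `prob-hellinger`, `prob-tv`,
  `prob-chisq` view compositions as discrete distributions. Each family has a
  conditionally negative definite squared distance $\delta$ (Jensen–Shannon
  divergence with natural logarithm and $0\log 0 = 0$; squared Hellinger
  $\sum_j (\sqrt{x_j}-\sqrt{y_j})^2$; total variation
  $\tfrac12\sum_j |x_j-y_j|$; chi-square $\sum_j (x_j-y_j)^2/(x_j+y_j)$ with
  $0/0 = 0$), turned into a positive semi-definite kernel by *anchoring*:
  $$k(x, y) = \tfrac12\left[\delta(x, u_0) + \delta(y, u_0) -
  \delta(x, y)\right],$$ with anchor $u_0$ the barycenter by default. This
  construction was chosen over alternatives because $\delta$ decomposes as a
  sum over components, which is exactly the structure required by the
  weighting scheme below. All four tolerate zeros.
* **Riemannian manifold** — `heat-diffusion`,
  $\exp(-d_g^2(x,y)/(4t))$ with the spherical geodesic
  $d_g(x, y) = 2\arccos\left(\sum_j \sqrt{x_j y_j}\right)$ (argument clipped
  to $[-1, 1]$), motivated by the information geometry of the multinomial
  family and empirically strong on sparse data. We drop the constant
  prefactor $(4\pi t)^{-(p-1)/2}$ of the heat-kernel approximation — it is a
  positive rescaling that underflows at large $p$ and cancels in ridge
  regression after re-tuning $\lambda$. The geodesic Gaussian is only
  approximately positive semi-definite, so square Gram matrices of this
  family are spectrally repaired (negative eigenvalues clipped to zero, with
  a warning) before entering any solver.

Every kernel induces a semi-metric
$d_k(x,y) = \sqrt{k(x,x) - 2k(x,y) + k(y,y)}$ (`induced_distance()`), which
the embedding and summary tools reuse.

### The default grid

`default_kernel_grid()` returns 55 kernels, all data-adaptive and
deterministic given the table: the linear kernel; 4 RBF bandwidths around the
median heuristic ($g = g_0 \cdot \{0.1, 1, 10, 100\}$ with $g_0$ the
reciprocal median squared distance); 5 Aitchison shifts
$c = \tfrac12\min_{x>0} x \cdot 10^{\{-2..2\}}$ centered at half the minimum
non-zero abundance; 10 Aitchison-RBF combinations (5 shifts × 2 clr-space
median-heuristic bandwidths); 24 probability kernels (4 families × 2 anchors,
barycenter and data mean, × 3 distance scalings $\{0.5, 1, 2\}$); and 11
diffusion times log-spaced in $[10^{-2}, 10^1]$. The count of 55 is a
deliberate default: with 10 outer folds, 5 inner folds and a penalty grid of
size 10 the selection performs exactly $55 \times 10 \times 5 \times 10 =
27{,}500$ model fits, which the implementation audits with a counter.

## Interpretation on the simplex

Two coordinate-wise perturbations stay on the simplex:

* $\psi_j(x, c)$ multiplies $x_j$ by $c \ge 0$ and re-closes:
  the $j$-th part becomes $c x_j / (1 + (c-1)x_j)$, every other part is
  divided by the same denominator.
* $\phi_j(x, z)$ fixes $x_j = z \in [0,1]$ and rescales the rest
  proportionally by $(1-z)/(1-x_j)$.

The **compositional feature influence** (CFI) of component $j$ is
$I_j = E\!\left[\tfrac{d}{dc} f(\psi_j(X, c))\big|_{c=1}\right]$, estimated by
a central finite difference (default $h = 10^{-4}$, error $O(h^2)$) averaged
over samples. The **compositional perturbation dependence** (CPD) is the curve
$S_j(z) = E[f(\phi_j(X, z))] - E[f(X)]$, estimated by plug-in means. Key
properties, each of which is a test:

* For $f(x) = \beta^\top\log(x)$ with $\sum\beta_j = 0$: CFI $= \beta$ exactly
  and $S_j(z) = \beta_j \log\frac{z}{1-z} + \text{const}$, with $S_j \equiv 0$
  when $\beta_j = 0$. CFI and CPD thus generalize log-contrast coefficients to
  arbitrary differentiable models.
* CFI values always sum to zero: the chain rule gives the per-sample
  derivative $x_j(\partial_j f - \sum_\ell x_\ell \partial_\ell f)$, which
  telescopes over $j$. A "total influence" on the simplex is necessarily
  relative.
* CPD values at $z$ outside the observed support of $X_j$ are extrapolations
  of the fitted model; the default grid therefore spans only the 5%–95%
  quantile range of the observed component, and samples with $x_j = 1$ (for
  which $\phi$ is undefined at $z<1$) are dropped with a warning rather than
  failing the whole estimate.

## Prior-knowledge weighting

Relations between components (taxonomy, phylogeny) enter through a symmetric
positive semi-definite matrix $W \ge 0$. For kernels with componentwise
structure $k(x,y) = \sum_j k_0(x_j, y_j)$ — the linear kernel and all four
probability families — the weighted kernel is
$$k_W(x, y) = \sum_{i,j} W_{ij}\, k_0(x_i, y_j),$$
which is again positive semi-definite. The Aitchison kernel is weighted as the
quadratic form $\mathrm{clr}_c(x)^\top W\, \mathrm{clr}_c(y)$; the RBF-type
families exponentiate the corresponding $W$-quadratic-form squared distance.
For the weighted heat-diffusion kernel the geodesic has no quadratic form, so
we use the chordal small-angle surrogate
$4(\sqrt{x}-\sqrt{y})^\top W(\sqrt{x}-\sqrt{y})$; with $W = I$ this is an
approximation of (not identical to) the unweighted geodesic kernel, a
deliberate trade made to keep the weighted family a single formula.

`partition_weights()` builds the block matrix $W_{ij} = \sum_\ell
\tfrac{1}{|P_\ell|}\mathbf{1}\{i, j \in P_\ell\}$ from a partition
$P_1, \dots, P_m$ of the components. Each block contributes a rank-one
projector (eigenvalues 0 and 1), and the weighted-Aitchison RKHS collapses to
log-contrast functions whose coefficients are *constant within blocks* — so
the CFI of a partition-weighted model is equal within blocks, which the test
suite checks both algebraically (by projecting the implied coefficient
vector) and empirically (within-block CFI spread below 5% of the across-block
spread).

`tree_weights()` derives $W$ from a phylogenetic tree as
$\exp(-D_{ij}/\text{bandwidth})$ of patristic distances, followed by spectral
clipping and diagonal rescaling to one. This is a pragmatic stand-in for
UniFrac-style constructions, clearly flagged as such; a user-supplied weight
matrix (labeled delimited text, `read_weight_matrix()`) always takes
precedence. Validation clips eigenvalues in $[-10^{-8}\lambda_{max}, 0)$ and
hard-errors below that.

## Model selection

`select_kernel()` implements a two-step hierarchical cross-validation:

1. For each kernel: split into $N_{out}$ outer folds (stratified for
   classification); for each outer fold, an $N_{in}$-fold inner CV on the
   remaining folds picks $\tilde\lambda$ from the grid; the outer fold is then
   scored (negative RMSE or balanced accuracy) by the model fit with
   $\tilde\lambda$. The kernel with the best mean outer score wins.
2. `refit_lambda()` re-selects $\lambda$ for the winning kernel by
   $N_{in}$-fold CV on the full data and refits on all samples.

Defaults: $N_{out} = 10$, $N_{in} = 5$, 10 penalties log-spaced in
$[10^{-6}, 10^3]$. Determinism: folds derive only from the seed (inner folds
additionally from the outer-fold index), so every kernel is scored on
identical splits and reruns are bit-identical. Tie-breaking is by grid order
for kernels and towards the *larger* penalty for $\lambda$ (the conservative,
more-regularized choice). Implementation note: each inner training fold is
eigendecomposed once and all penalties solved in that basis, so the grid is
effectively free; the audit counter still counts each (fold, penalty) pair as
a fit, giving the documented $K \cdot H \cdot N_{in} \cdot N_{out}$ total.

## Embedding and summaries

`kpca()` double-centers the Gram matrix, eigendecomposes, and scales
eigenvectors by $\sqrt{\lambda}$; signs are fixed by making the
largest-magnitude eigenvector entry positive. Out-of-sample scores use the
standard centered projection with training-set statistics. `pc_influence()`
reports, for each component and principal axis, the CFI of the out-of-sample
score function — the minimal way to make per-component loadings meaningful
under the unit-sum constraint; like every CFI, each column sums to zero.

`closeness_score()` is $D(x) = -d_k^2(x, u)$ for a reference $u$;
`geometric_median()` picks the observation minimizing total induced distance
within a group (ties to the lowest index), e.g. the center of a healthy
subgroup for a kernel health score. `alpha_diversity()` uses the barycenter
as $u$: a data-adaptive diversity aligned with the fitted kernel. For the
linear kernel, expanding $-\|x - u\|^2$ gives exactly
$$D(x) = \left(1 - \sum_j x_j^2\right) - \frac{p-1}{p},$$
the Gini–Simpson index shifted by $(p-1)/p$. A shift constant of $(p-2)/p$
circulates in print for this identity; direct algebra (and the check at
$p = 2$, $x = (1,0)$: $D = -1/2$, Gini–Simpson $= 0$) gives $(p-1)/p$, and the
package asserts the derived constant. The diversity makes no axiomatic
claims; it is symmetric, interpretable, and consistent with the kernel
actually used for modeling.

## Synthetic data: the stated world

`sample_logistic_normal()` draws $X = \mathrm{closure}(\exp Z)$,
$Z \sim N(\mu, \Sigma)$, with defaults $\mu = 0$, $\Sigma = I$. The defaults
are deliberately plain: the CFI/CPD recovery laws are distribution-free, so
any nondegenerate covariate law verifies them, and the identity covariance
avoids smuggling structure into tests that claim generality.
`zero_inflate()` resamples each row as $\mathrm{multinomial}(d, x)/d$ — the
mechanism by which finite sequencing depth produces zeros — so a component at
abundance $x_j$ drops out with probability $(1-x_j)^d$. `block_dgp()`
generates log-contrast responses whose coefficients are block-constant
(`dgp1`, where partition weights are informative) or split $\pm$ within
blocks (`dgp2`, where the same weights are adversarial), with defaults
$\beta_B = 2$, $\beta_P = -1$, noise SD 1; coefficients are re-centered to
zero-sum within the designated blocks so the null components keep exactly
zero coefficients.

What the generators do *not* emulate: taxon-correlated covariance,
overdispersion beyond multinomial, batch effects, or the abundance profiles
of any real cohort. A green test therefore establishes algebraic and
statistical correctness of the machinery under a clean compositional world,
not benchmark performance on real microbiome data.

Simulation-based tests fix 20 seeds and assert regression-style bounds (e.g.
an Aitchison-family kernel wins model selection on log-contrast data in at
least 16/20 replicates; fitted-model CFI error at $n = 300$ below
$0.15\,\|\beta\|_\infty$). The "heavy regularization under pure noise" check
defines heavy as $\lambda \ge 1$, the point where $n\lambda$ dominates the
clr-Gram spectrum and predictions collapse to the training mean.

## Numerical choices

* Simplex tolerance: row sums within $10^{-9}$ pass silently; deviations up
  to $10^{-6}$ are re-closed with a warning; beyond that, rejection. Count
  tables are closed (with a message) only by the explicit loader.
* Finite-difference step $h = 10^{-4}$ for CFI and path derivatives:
  truncation error $O(h^2) \approx 10^{-8}$, well below the $10^{-6}$
  guarantees, while staying clear of cancellation at double precision.
* Degenerate perturbations ($x_j = 1$ for $\phi$ at $z < 1$, or $c = 0$ at
  $x_j = 1$ for $\psi$) skip the affected samples with a warning and report
  the count used, rather than failing the estimate.
* The ridge solver reports a structured numerical error advising a larger
  $\lambda$ if the system is singular; no silent jitter is added.
* Indices are positional internally; all I/O joins tables, trees and weight
  matrices by component *label*, and mismatches are hard errors.

## Known limitations

* `tree_weights()` is a similarity heuristic, not UniFrac.
* The probability-kernel group is limited to the four named distances; no
  generalized one- or two-parameter families.
* No sparse/low-rank approximations: $O(n^3)$ solves cap practical $n$ at a
  few thousand on one CPU.
* Classification is ridge-on-labels; an SVM backend would be a natural
  extension but is not provided.
* CPD curves outside the observed support reflect model extrapolation and
  should not be over-read.
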