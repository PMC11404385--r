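---
title: "GLM-PO2PLS: model, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GLM-PO2PLS: model, estimation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glmpo2pls)
```

## The model

Many studies measure two omics blocks — say methylation ($x$, $p$ features)
and glycomics ($y$, $q$ features) — on the same $N$ subjects, together with
an outcome $z$ (a continuous trait or a disease status). Studying each block
against the outcome separately ignores the correlation between the blocks.
GLM-PO2PLS is a one-stage latent-variable model for the triple $(x, y, z)$:

$$
x = t W^\top + t_\perp W_\perp^\top + e, \qquad
y = u C^\top + u_\perp C_\perp^\top + f, \qquad
u = t B + h, \qquad
\eta(\mathrm{E}[z]) = a_0 + t a^\top + u b^\top .
$$

The paired joint components $t, u$ (length $K$) carry the covariation
shared between the blocks; $t_\perp, u_\perp$ ($K_x$, $K_y$) carry
structured variation specific to one block; $e, f, g$ are isotropic
residuals. The diagonal, positive inner relation $B$ ties $u$ to $t$, with
the *heterogeneity* $h \sim N(0, \Sigma_h)$ the part of $u$ that $t$ does
not explain. All latent covariances are diagonal; loading matrices are
semi-orthogonal. The link $\eta$ is the identity for a gaussian outcome and
the logit for a Bernoulli outcome.

Because $u = tB + h$, the linear predictor can be rewritten as
$a_0 + t\tilde a^\top + h \tilde b^\top$ with $\tilde a = a + B b^\top$ and
$\tilde b = b$. This reduces the near-collinearity of $t$ and $u$ in the
outcome equation; $\tilde a$ is the *total* effect of the $x$-side joint
structure and $\tilde b$ the *direct* effect of the $y$-side heterogeneity.
The package stores and reports the tilde parameterization throughout and
omits the tildes (`reparameterize()` converts raw $(a, b)$ coefficients).

The model is identified up to per-component sign flips under the usual
conditions (semi-orthogonal loadings, full-rank stacked loadings, positive
$B$ with strictly decreasing $\mathrm{diag}(\Sigma_t B)$); `validate_params()`
checks them and `canonicalize_signs()` fixes the gauge by making the
largest-magnitude entry of each reference loading column positive (ties
broken by the first index, so the canonical form is deterministic).

For a gaussian outcome (centered, $a_0 = 0$), $(x, y, z)$ is jointly
zero-mean normal with a structured covariance built from low-rank loading
terms plus diagonal noise; `build_joint_covariance()` returns it together
with the sub-covariances the algorithms use. For a Bernoulli outcome the
linear predictor (not $z$ itself) is normal and the same structure holds
with the $z$ row holding the predictor covariance.

## Estimation

### Gaussian outcome: exact EM

The observed vector is a linear-Gaussian function of the latent vector
$\zeta = (t, u, t_\perp, u_\perp)$, so the E-step is exact Gaussian
conditioning. All E-step quantities are computed through the latent-space
(Woodbury) factorization: the posterior covariance
$(\Sigma_\zeta^{-1} + \Lambda^\top D^{-1}\Lambda)^{-1}$ is shared by all
subjects, and no $(p+q+1)^2$ matrix is ever inverted — cost is linear in
$p + q$, which is what makes the $p = 2000$ simulation cells and the
repeated-fit experiments cheap.

The M-step maximizes the factorized expected complete-data log-likelihood
blockwise, and every block update is an *exact* coordinate maximizer:

* $(\hat a, \hat b) = z^\top \mathrm{E}[(t,h)]\,
  \mathrm{E}[(t,h)^\top (t,h)]^{-1}$, then the residual variance
  $\sigma_g^2$ in closed form;
* each semi-orthogonal loading block solves an orthogonal Procrustes
  problem: on the Stiefel manifold the quadratic term
  $\mathrm{tr}(W^\top W S)$ is constant, so the polar factor of the
  regression cross-product is the exact constrained maximizer ($W$ and
  $W_\perp$ are alternated twice);
* latent variances come from conditional second moments; the diagonal $B$
  update solves a small linear system that includes the outcome term
  (which involves $B$ through $h = u - tB$), keeping the update an exact
  coordinate maximizer rather than ignoring that coupling.

Exact blockwise maximization makes the algorithm a monotone generalized
EM: the observed-data log-likelihood trace never decreases (asserted in
the tests to $10^{-8}$). Loadings are re-orthogonalized every iteration as
part of the Procrustes updates rather than once at convergence; this keeps
every iterate inside the identified parameter space.

Initialization is method-of-moments: $W, C$ from the top-$K$ singular
triplets of $x^\top y$; specific loadings from blocked power iteration on
the residual blocks; variances from explained-variance splits; $(a, b)$
from a regression of $z$ on the initial scores. Convergence is declared
when the relative log-likelihood change drops below `tol` ($10^{-6}$ by
default, `max_iter` $10^4$).

### Bernoulli outcome: quadrature EM with a gradient M-step

With a logit link the marginal likelihood integrates over the latent space.
Conditional on $\nu = (t, u)$ the outcome is independent of everything
else, so the specific components are integrated out analytically and only
a $2K$-dimensional integral over $\nu$ remains. It is approximated by a
tensor-product Gauss–Hermite rule: standard nodes $\nu^*$ are mapped
through $\nu = \sqrt{2}\, \nu^* R$ with $R$ the Cholesky factor of
$\Sigma_\nu$, and the product weights are normalized by $\pi^{-d/2}$ with
$d = 2K$ — the unique normalization making $\int 1 \cdot f(\nu)\,d\nu = 1$
(asserted to $10^{-10}$). Note the grid is genuinely $2K$-dimensional.
All per-node densities are accumulated in log space with log-sum-exp.

The coefficient block $\beta = (a_0, a, b)$ has no closed-form update;
each EM iteration takes **one** gradient step along $\nabla Q_\beta$ with
a backtracking (Armijo) step size: start at $s = 1$, shrink $s \leftarrow
0.8 s$ until $Q(\beta + s\nabla Q) \ge Q(\beta) + 0.5\, s\, \|\nabla
Q\|^2$. $Q_\beta$ and its gradient are evaluated on the same quadrature
grid using the posterior node weights, so the ascent condition refers to
the actual objective being maximized. The remaining blocks reuse the
gaussian M-step machinery: quadrature moments of $\nu$ are extended to the
specific components by exact Gaussian conditioning of $(t_\perp, u_\perp)$
given $(\nu, x, y)$ — their conditional law is Gaussian even though they
were integrated out of the likelihood. The $B$ update under this family
uses the latent-relation term only (the logistic outcome term has no
closed-form coordinate update), which is why the binary trace is asserted
monotone to the looser $10^{-6}$.

The default $M = 16$ nodes per dimension gives $256$ grid points at
$K = 1$; the grid grows as $M^{2K}$, so the binary model is intended for
small $K$ (a hard error above $10^6$ points). The node transformation is
scaled by the *prior* covariance of $\nu$; when the data are very
informative the per-subject posterior is much narrower than the prior and
moments converge more slowly in $M$ — the oracle tests therefore use toys
whose noise is of the same order as the signal, and users with small $p$
and small noise should increase `M`.

## Inference

The association between the outcome and the omics is tested through
$\alpha = (a, b)$: the full Wald statistic $T = \hat\alpha
\Pi_{\hat\alpha}^{-1} \hat\alpha^\top \sim \chi^2_{2r}$ (with $r = K$)
tests $a = b = 0$, and the component-wise statistic on the $(a_k, b_k)$
sub-block is referred to $\chi^2_2$. The covariance $\Pi_{\hat\alpha}$
comes from the Louis observed information, assembled from conditional
expectations of the complete-data score and negative Hessian of the
outcome term only — using the approximation that $\hat\alpha$ is
asymptotically independent of the remaining parameters and that
$\hat\sigma_g^2$ is treated as fixed. The printed double-sum form of the
information is implemented literally, including the cross-subject term
$\sum_{i \ne j} \mathrm{E}[S_i]\mathrm{E}[S_j]^\top$; at the MLE the total
conditional score is numerically zero, so this term is negligible, but it
is kept for fidelity. For the gaussian family the required conditional
fourth moments have closed forms; for the Bernoulli family they are
quadrature sums, and all binary p-values carry a caveat flag because
asymptotic normality of that estimator is assumed, not derived.

`test_omics_association()` applies the same construction to the
complete-data term of the latent regression $u = tB + h$, giving a 1-df
Wald test of $B_k = 0$ per component pair — our interpretation of the
inner-relation p-values this model family reports; it is invariant under
the allowed sign flips.

In the simulation study this machinery reproduces the expected operating
characteristics: empirical power 1 under the alternative, type-I error
near 5% at $N = 1000$ and mildly inflated at $N = 100$ (the acceptance
tests and `scripts/acceptance.R` recompute these).

## The simulator

`sim_scenario()` + `simulate_dataset()` generate data from the model
itself, which is the package's only data source for tests and experiments.
Defaults follow the study grid this model family was evaluated on:

* coefficients $a = 2$, $b = 1$; $B = I$; one joint and one specific
  component per block;
* latent variances at the standard-normal convention ($\Sigma_t = 1$;
  for $K \ge 2$ a decreasing sequence $K..1$ keeps
  $\mathrm{diag}(\Sigma_t B)$ strictly decreasing — the multi-component
  setting is not pinned down by the study, so this is our choice);
* heterogeneity as a fraction of $\mathrm{var}(u)$ (moderate 0.4 / high
  0.8), implemented by scaling $\Sigma_h$ only while $\Sigma_t$ stays
  fixed: $\Sigma_h = \frac{het}{1-het} B^2 \Sigma_t$;
* noise fractions as *trace ratios* of expected variance (low 40%/40%,
  high 95%/5% for $x$/$y$; 20% for the continuous outcome). The trace
  ratio is the standard reading of a "noise proportion" and, e.g.,
  $\sigma_e^2 = \frac{noise_x}{1-noise_x} (\mathrm{tr}\,\Sigma_t +
  \mathrm{tr}\,\Sigma_{t_\perp})/p$;
* true loading pairs $[W\,W_\perp]$ (and $[C\,C_\perp]$) are drawn
  standard normal and orthogonalized jointly, so specific subspaces are
  orthogonal to joint ones — the cleanest reading of "specific";
* one master seed expands into fixed sub-streams (loadings, latents,
  noise), so every scenario cell is reproducible component-wise.

What the simulator does *not* emulate: real methylation beta-value
distributions (bounded, skewed), family or batch structure, covariate
effects, missing values, or feature correlation beyond the low-rank-plus-
diagonal structure. Passing tests on these data demonstrate correctness
of the algorithms under the model's own assumptions, not robustness to
model misspecification.

`simulate_null_outcome()` implements the null protocol for size
experiments: $z \sim N(0,1)$ drawn independently of $(x, y)$.

## Numerical choices and degenerate inputs

* Variance floors at $10^{-12}$ ($10^{-8}$ at initialization) prevent
  collapse of any variance block; a non-positive-definite conditioning
  block raises an informative error.
* Singular latent second-moment matrices (too many components) raise an
  error suggesting a smaller $K$.
* A binary outcome with no variation aborts with a separation error; the
  backtracking step underflowing below $10^{-12}$ skips the update with a
  warning (flat region).
* Ties in the sign gauge and in the top-fraction feature ranking are
  broken by the first index.
* Probabilities at 0/1 are clipped before the logit-scale RMSEP, with a
  warning.

## The evaluation harness

`run_type1_experiment()`, `run_power_experiment()` and
`run_scenario_grid()` drive the simulation study: per-replicate fits,
full-test rejections, scaled coefficient errors $(\hat a - a)/a$, loading
inner products, top-25% feature-recovery TPR and test-set RMSEP (on the
logit scale of the true probability for binary outcomes, which exists only
on simulated data). Ridge regression on a single block (glmnet, `alpha =
0`, 10-fold CV) provides the ridge-x / ridge-y comparators. Estimated
coefficients are sign-aligned to the truth before computing scaled errors,
since the model is only identified up to component signs.

Default replicate counts in the acceptance runs are scaled to desk size
(100–500 replicates rather than the original 500–10,000; test sets of
size 1000 are kept), with seeds fixed; the binomial Monte-Carlo error
implied by these counts is built into the test tolerances. Problem sizes
used by the shipped experiments: $N \in \{100, 1000\}$, $p \in \{100,
2000\}$, $q \in \{10, 25\}$, $K = K_x = K_y = 1$.

## Choosing component numbers

`scree()` returns the singular values of $x^\top y$ and the eigenvalues of
the deflated $x^\top x$ and $y^\top y$, computed through $N$-dimensional
Gram matrices (never a $p \times p$ product). The suggested counts use a
largest-successive-ratio-drop heuristic; this heuristic is the package's
own addition — inspecting the scree plot is the intended workflow, and
cross-validated selection is out of scope.

## Known limitations

* Two omics blocks only; diagonal latent covariances; no missing data.
* The binary model is practical only for small $K$ (tensor quadrature),
  and its p-values rest on an assumed asymptotic normality.
* Gaussian-family intercepts are handled by centering; the binary
  intercept $a_0$ is estimated.
* The prior-scaled (non-adaptive) quadrature can need large `M` when the
  omics are extremely informative relative to the latent prior.
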