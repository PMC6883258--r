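---
title: "Testing mediation with high-dimensional, correlated mediators"
author: "hdma package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing mediation with high-dimensional, correlated mediators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdma)
```

## The model

Epigenome-wide mediation studies ask which of many correlated molecular
markers — typically DNA methylation M-values at tens of thousands of CpG
sites — transmit the effect of an exposure $X$ (alcohol use, childhood
maltreatment, ...) to an outcome $Y$ (disease status). With mediators
$M_1, \dots, M_k$ the model is the standard regression system

$$
\begin{aligned}
E(Y) &= \theta_1 + c X,\\
M_j &= \theta'_j + a_j X + \varepsilon_j, \qquad j = 1, \dots, k,\\
E(Y) &= \theta_2 + c' X + \textstyle\sum_{j=1}^k b_j M_j,
\end{aligned}
$$

with a logit link on the two outcome equations when $Y$ is binary. The
indirect effect through $M_j$ is the product $a_j b_j$; the total effect
decomposes as $c = c' + \sum_j a_j b_j$. Mediator $j$ carries a mediation
effect when **both** $a_j \neq 0$ and $b_j \neq 0$.

The statistical difficulty sits entirely in the third equation: $k$ can
exceed $n$ by orders of magnitude, and neighbouring CpG sites are strongly
correlated. Penalized regression (lasso, MCP) handles the dimension but its
estimates are biased by construction and carry no standard errors, so it
cannot feed a per-mediator test directly.

## The testing pipeline

`hdma_test()` runs four stages.

**1. Sure independence screening.** Mediators are ranked by the
standardized marginal association $|\hat\beta_j| / \widehat{se}_j$ of $M_j$
in the single-mediator outcome regression $Y \sim X + M_j$ (plus
covariates), and the top $d = \lceil n / \log n \rceil$ are retained
(`screening_dimension()`, `marginal_screen()`). The divisor is
configurable ($n / (2\log n)$ is conventional at larger $n$). Screening on
the exposure-to-mediator equation is also available
(`sis_basis = "mediator_model"`), but the outcome-model basis is the
default for both families for a structural reason we found decisive in
simulation: under AR(1) correlation $\rho = 0.8$, a-path screening removes
mediators whose exposure path is null but whose outcome path is not, and
the omission of their signal from the joint outcome model biases the
coefficients of correlated neighbours so badly that null mediators adjacent
to true ones are rejected in the majority of replications. Outcome-model
screening keeps those mediators in the model and preserves type-I control.
Its cost is a mild post-selection optimism in $p_b$ for null mediators that
are only marginally retained; with the default variance form the joint
type-I rates of the exposure-associated nulls stay within Monte-Carlo
range of the nominal 0.05 in all replication cells (the published table
reports values as low as 0.02 at $\rho = 0$, which the reuse effect makes
hard to reach exactly).

**2. De-sparsified lasso inference on the outcome model.** Over the $d$
retained mediators (exposure and covariates unpenalized), the lasso
estimate $\hat b^{\text{lasso}}$ is bias-corrected column by column. In the
linear case (`debias_linear()`), with $Z_j$ the residual of the nodewise
lasso regression of $M_j$ on the other columns,

$$
\hat b_j \;=\; \frac{Z_j^\top Y}{Z_j^\top M_j}
\;-\; \sum_{l \neq j} \frac{Z_j^\top M_l}{Z_j^\top M_j}\,
\hat b^{\text{lasso}}_l,
\qquad
\widehat{se}_j = \frac{\hat\sigma_\varepsilon \lVert Z_j\rVert_2}
{\lvert Z_j^\top M_j\rvert},
$$

where $\hat\sigma_\varepsilon$ comes from the scaled lasso
(`scaled_lasso_sigma()`: alternating coefficient and noise-scale updates
with penalty $\lambda = \hat\sigma \sqrt{2 \log p / n}$). In the logistic
case (`debias_logistic()`) the design (including the intercept column) is
weighted by $\sqrt{\hat\mu(1 - \hat\mu)}$, nodewise lasso on the weighted
design builds rows of an approximate inverse information $\hat\Theta$, the
corrected estimate is
$\tilde\beta = \hat\beta - \hat\Theta\,\nabla \ell_n(\hat\beta)$ with
$\ell_n$ the average negative log-likelihood, and the per-coefficient scale
is the weighted-design (Fisher) covariance
$\hat\sigma_j^2 = (\hat\Theta \hat\Sigma \hat\Theta^\top)_{jj}$,
$\hat\Sigma = n^{-1} X_w^\top X_w$ — the form the reference nodewise
algorithm uses. The empirical score-outer-product sandwich
$\big(\hat\Theta\, [n^{-1}\sum_i \dot\ell_i \dot\ell_i^\top]\,
\hat\Theta^\top\big)_{jj}$ is available via `glm_variance = "sandwich"`;
the two coincide asymptotically, but in the replication cells the sandwich
runs visibly anti-conservative for null coefficients correlated with true
signals ($n = 300$, $d = 53$, $\rho = 0.8$: null rejection around
0.15–0.16 against 0.07–0.12 for the Fisher form), so the Fisher form is
the default. Two-sided normal p-values
$P_{j,b} = 2\{1 - \Phi(\sqrt n\,|\tilde\beta_j| / \hat\sigma_j)\}$ follow
from the estimator's asymptotic normality. In the unpenalized,
well-conditioned limit both routines reduce exactly to OLS / maximum
likelihood — the test suite asserts this to $10^{-8}$.

**3. Exposure-to-mediator tests.** For each retained mediator,
$\hat a_t$ is ordinary least squares of $M_t$ on $X$ (plus covariates) with
$P_{t,a} = 2\{1 - \Phi(|\hat a_t| / \hat\sigma_t)\}$ (`fit_alpha_path()`).
The normal reference is used, as is conventional at these sample sizes; the
difference from the $t$ reference is negligible for $n \gtrsim 100$.

**4. Intersection-union test.** Mediation is declared for $M_t$ only when
both path tests reject: $P^*_t = \max(P_{t,a}, P_{t,b}) < \alpha$ with
$\alpha = 0.05$ by default and no multiplicity correction, matching the
procedure being reproduced (Bonferroni/BH adjustment of $P^*$ is available
via `p_adjust`). Indirect effects are summarised as
$\hat a_t \hat b_t$ and as a percentage of the total effect,
$|\hat a_t \hat b_t| / |\hat c| \times 100$ — the absolute-value convention
is the only one consistent with published examples in which individual
products and the total effect have opposite signs.

## The MCP comparator

`hima_test()` implements the selection-plus-refit strategy the pipeline is
compared against: the same SIS stage, then an MCP-penalized outcome
regression (minimax concave penalty, concavity $\gamma = 3$, penalty chosen
by BIC over a 50-point log grid), then an ordinary refit of the survivors
whose Wald tests supply $p_b$, and the same intersection-union rule. The
refit p-values ignore the selection event; that optimism is a property of
the comparator and is deliberately not corrected. The coordinate descent
(`fit_mcp()`, compiled) uses the firm-threshold update — soft-thresholding
scaled by $(1 - 1/\gamma)^{-1}$ inside $|z| \le \gamma\lambda$, the
unpenalized solution beyond — and, for the logistic loss, quadratic
majorization with curvature $1/4$ plus adaptive rescaling of the concavity
region so that $\gamma = 3$ remains valid for any weight.

## Tuning parameters

| parameter | default | role |
|---|---|---|
| `alpha` | 0.05 | level of both path tests and the joint test |
| `sis_divisor` | 1 | retains $\lceil n/(\text{divisor}\cdot\log n)\rceil$ mediators |
| `sis_basis` | outcome_model | screening regression (see above) |
| `lambda` | CV | coefficient-lasso penalty (10-fold CV, `lambda.min`) |
| `nodewise_lambda` | "cv" | per-column 10-fold CV of nodewise penalties |
| `mcp_gamma` | 3 | MCP concavity |
| `weight_floor` | 1e-8 | lower clip on logistic variance weights |

All fitting standardizes columns internally and reports on the original
scale; the exposure, covariates and intercept are never penalized (the
inferential target is $b$, and shrinking $c'$ would distort the
decomposition). Coordinate-descent tolerances are $10^{-7}$ on coefficient
changes.

`harness_control()` is the variant the Monte-Carlo harness runs with: the
nodewise penalty is cross-validated (5-fold, 30-point path) on five probe
columns and the geometric mean applied to every column. Per-column CV costs
roughly an order of magnitude more at $d \approx 100$ while changing the
projection residuals imperceptibly here, because all nodewise columns share
the same AR(1) scale; the shared mode makes a 200-replication cell cost
minutes instead of hours on one core.

## The synthetic-data generator

`simulate_mediation()` reproduces the simulation design of the study being
replicated: exposure $X_i \sim \text{Bernoulli}(0.74)$ (the drinking
prevalence of the motivating case-control study), mediators
$M_i \sim \text{MVN}(\theta' + a X_i, \Sigma)$ with $\theta' = 1$ and
$\Sigma_{st} = \rho^{|s-t|}$, and a binary outcome with
$\eta_i = -4.5 + c' X_i + \sum_j b_j M_{ij}$,
$Y_i \sim \text{Bernoulli}(\text{logit}^{-1}(\eta_i))$. The sparse
coefficient vectors are fixed by the design:
$b = (0.8, 0.7, 0.6, 0.5, 0, 0, 0.5, 0.5, 0, \dots)$ and
$a = (0.35, 0.25, 0.35, 0.55, 0.55, 0.55, 0, 0, 0, \dots)$, so mediators
1–4 are true mediators, 5–6 are exposure-associated nulls, 7–8 are
outcome-associated nulls, and the remaining $k - 8$ are complete nulls —
the two distinct kinds of null are distinguishable in the `truth_class`
metadata. The true total effect is $0.94$ under complete mediation
($c' = 0$) and $1.44$ at $c' = 0.5$.

Two exact MVN samplers are provided: a Cholesky factorization and an
$O(nk)$ AR(1) recursion (the default; the test suite checks their
distributional agreement). A continuous outcome uses the same linear
predictor with unit Gaussian noise — the published study simulates only the
binary family, and the unit scale is simply the conventional choice that
keeps the signal-to-noise ratio comparable. The generator does **not**
emulate beta-mixture methylation distributions, batch effects or cell-type
composition; passing the replication study therefore demonstrates the
statistical behaviour of the testing procedure under the stated generative
model, not robustness to the full messiness of array data.

## The replication harness

`run_power_study()` replicates cells of the $(n, k, \rho, c')$ grid with
both methods run on the *same* generated datasets (paired seeds — the
published comparison uses marginal rates, so pairing only reduces the
variance of differences). Per-replication seeds are
`seed_base + 10^5 * (cell - 1) + r`, making results independent of worker
count and execution order. Mediators screened out or dropped by the penalty
count as non-rejections. Failed replications (e.g. separation) are excluded
from the denominator and reported.

The default is 200 replications per cell; the published table uses 1000.
At 200 replications the Monte-Carlo standard error of a rate $r$ is
$\sqrt{r(1-r)/200}$ (about 0.03 at $r = 0.5$), which is the resolution the
package's own acceptance checks state. The acceptance script exercises the
cells $(300, 100, 0)$, $(300, 1000, 0.8)$ and $(600, 1000, 0.8)$; at these
sizes a cell costs roughly two to six minutes on one core with
`harness_control()`.

## Numerical choices and degenerate inputs

* $d = n/\log n$ is rounded **up** — the only convention consistent with
  both published worked values (27 at $n = 128$, divisor 1; 34 at
  $n = 398$, divisor 2); the natural logarithm is used.
* Screening ties are broken by ascending column index; constant or
  separated mediator columns score 0 with a warning rather than failing
  the screen.
* Nodewise degeneracy ($Z_j^\top M_j$ numerically zero, e.g. perfectly
  collinear columns on the exact path) is a hard error naming the column.
* `lambda = 0` requests are routed to exact OLS / IRLS rather than the
  penalized solver.
* Logistic fits guard against separation (error) and weight underflow
  (floor at `weight_floor`).
* Mediators outside the retained set are reported with status
  `"not_retained"` — never as $p = 1$ — preserving the distinction between
  untested and tested-null; MCP non-survivors are `"not_selected"`.

## Known limitations

* The $p_b$ p-values inherit the finite-sample behaviour of de-sparsified
  inference: slightly optimistic for null coefficients when $d$ is an
  appreciable fraction of $n$ and the design is strongly correlated, and
  additionally for mediators that barely survived an outcome-based screen
  (see above). Joint type-I error for exposure-associated nulls sits at or
  somewhat above 0.05 rather than below it as in the published table.
* No exposure–mediator interactions, multiple exposures, or epistatic
  structure; effects are assumed linear on the link scale.
* Real methylation workflows need upstream normalization, batch and
  cell-type adjustment; the package takes a clean numeric matrix (M-values
  via `beta_to_m()` if needed) and an explicit covariate matrix.
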