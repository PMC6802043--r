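---
title: "Methods: phylogenetic multilevel meta-analysis of ensemble range shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic multilevel meta-analysis of ensemble range shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangemeta)
```

## The model

Ensemble niche modelling gives each species several projected range
sizes, one per ecological niche model (ENM). `rangemeta` treats the
ensemble as replicate measurements of one quantity: the species'
proportional range shift. For species $i$ and ENM $j$,

$$D_{ij} = \frac{y_{ij} - x_{ij}}{x_{ij}} \times 100,$$

with $x$ and $y$ the baseline and future projected range sizes in grid
cells. The per-species effect size is the ensemble mean
$D_i = \bar{D}_{i\cdot}$ and its uncertainty the cross-ENM sample
variance $V_i$ (denominator $k-1$). The cross-species synthesis is a
multilevel random-effects meta-analysis:

$$D_i = \mathbf{x}_i'\boldsymbol\beta + u_{s,i} + u_{p,i} + e_i,
\qquad
u_s \sim N(0,\, T^2_s \mathbf{I}),\quad
u_p \sim N(0,\, T^2_p \mathbf{R}),\quad
e_i \sim N(0,\, V_i),$$

so the marginal covariance is
$\Sigma = T^2_s\mathbf{I} + T^2_p\mathbf{R} + \mathrm{diag}(V)$.
$\mathbf{R}$ is the Brownian-motion correlation among species implied by
the phylogeny: `brownian_vcv()` computes the shared root-to-ancestor
branch lengths $\mathbf{C}$ (via `ape::vcv`, cross-checked in the test
suite against a brute-force MRCA path-sum), and `vcv_to_correlation()`
normalizes to $R_{ij} = C_{ij}/\sqrt{C_{ii}C_{jj}}$.

We fit the **correlation** matrix, not the raw covariance, because branch
lengths are in arbitrary tree units; $T^2_p$ then carries the variance
scale in squared percent, directly comparable with $T^2_s$. A
`phylo_matrix: covariance` switch in `run_pipeline()` preserves the
alternative. Non-ultrametric trees are accepted; per-tip normalization
handles unequal depths.

Assumptions worth stating: effects are normal on the percent scale
(strongly right-skewed gains — a species can gain several hundred percent
but lose at most 100 — violate this in real data); $V_i$ is treated as
known although it is estimated from $k$ replicates; phylogenetic signal
in the *response to climate change* follows Brownian motion, which is a
modelling convenience, not a biological claim.

## REML estimation

`reml_engine()` maximizes the restricted log-likelihood

$$\ell_R(T^2_s, T^2_p) = -\tfrac12\left[(n-p)\log 2\pi + \log|\Sigma|
+ \log|\mathbf{X}'\Sigma^{-1}\mathbf{X}|
+ \mathbf{r}'\Sigma^{-1}\mathbf{r}\right]$$

with $\mathbf{r} = \mathbf{D} - \mathbf{X}\hat{\boldsymbol\beta}(\Sigma)$
and $\hat{\boldsymbol\beta}$ the GLS estimate. Numerical choices:

* **Parameterization.** Variances are optimized as $\gamma = \log T^2$,
  bounded in $[-30, 20]$; $\gamma$ at the lower bound is reported as
  $T^2 = 0$. The log scale keeps the boundary smooth and makes the
  delta-method SE of $T^2$ ($\widehat{SE}(T^2) = T^2 \cdot
  \widehat{SE}(\gamma)$, from a central-difference Hessian of $\ell_R$)
  well behaved.
* **Optimizer.** `nlminb` with the analytic gradient
  $\partial\ell_R/\partial T^2_k = -\tfrac12[\mathrm{tr}(\mathbf{P}\Sigma_k)
  - \mathbf{r}'\Sigma^{-1}\Sigma_k\Sigma^{-1}\mathbf{r}]$, relative
  tolerance $10^{-12}$, started from the DerSimonian–Laird moment
  estimate plus 3 random restarts (the surface is usually unimodal; the
  restarts guard against flat ridges when $T^2_p$ is weakly identified).
  A "false convergence" flag at a point satisfying first-order conditions
  is accepted as converged.
* **Linear algebra.** All solves go through one Cholesky factorization of
  $\Sigma$ per evaluation, so a 500-species fit takes a few seconds and
  the 1,205×1,205 scale of a full bird analysis remains a single-CPU
  computation.
* **Degenerate input.** If every $V_i = 0$ *and* the effects are exactly
  collinear with the design (e.g. all zero, as when future and baseline
  climates coincide), $\Sigma$ collapses; the engine returns a flagged
  degenerate fit ($\hat\beta$ = OLS, $T^2 = 0$) with a warning rather
  than failing, so a null pipeline yields $M = 0$. All-zero $V$ with
  varying effects is fine ($\Sigma = T^2\mathbf{I}$ stays positive
  definite).

Inference on $\boldsymbol\beta$ uses $t$ with $n - p$ degrees of freedom
by default (matching meta-regression tables that print $t$ statistics);
`test = "z"` switches to normal quantiles. The test suite validates the
engine two independent ways: an exhaustive zooming grid search of the
restricted likelihood at $n \le 8$, and agreement with `metafor`
(`rma` in the single-level limit to $10^{-6}$; `rma.mv` with the
phylogenetic structure).

## Heterogeneity statistics

* $Q = \sum w_i (D_i - \mathbf{x}_i'\hat\beta_{FE})^2$ with fixed-effects
  weights $w_i = 1/V_i$, $df = n - p$, chi-square reference. Zero $V_i$
  with non-identical effects are replaced by the smallest positive $V$
  (with a warning); identical effects give $Q = 0$ directly.
* $I^2$ uses the typical within-species variance
  $s^2 = (n-1)\sum w_i / [(\sum w_i)^2 - \sum w_i^2]$;
  $I^2_t = 100\,(T^2_s + T^2_p)/(T^2_s + T^2_p + s^2)$, and $I^2_s$,
  $I^2_p$ place one component alone in the numerator, so
  $I^2_s + I^2_p = I^2_t$ by construction.
* Pseudo-$R^2$ of a meta-regression is
  $\max(0,\, 1 - T^2_{mod}/T^2_{null})$, by default on the summed
  components (`r2_components = "species"` would use $T^2_s$ alone; both
  are defensible and the choice is exposed in `pseudo_r2()`).
* Reported per-species weights are $W_i = 1/(V_i + T^2_s + T^2_p)$,
  normalized — the classical random-effects weight, used for forest-plot
  circle sizes; the fit itself uses the full matrix
  $\Sigma^{-1}$, which generalizes these weights to correlated species.

## Moderator coding

Continuous moderators enter uncentered (so intercepts are the expected
shift at zero covariates, as in published meta-regression tables). The
IUCN threat category is a single ordinal numeric 0–4 (LC to CR): one
coefficient per category step. Migratory behavior is deviation-coded
(+1 absence, −1 presence), so its coefficient is the deviation of
migration absence from the midpoint of the two levels; with balanced
groups and no other terms it equals half the absence-minus-presence
difference. No multiplicity correction is applied across moderators.

## The two variance conventions

The ensemble variance of species $i$ can enter the model two ways, and
the package implements both (`variance_of_mean` in `species_effects()`
and `sim_effects_table()`):

* **Raw cross-ENM variance** $V_i$ (the default for projection data):
  the spread of the $D_{ij}$ themselves. This reads the ensemble
  disagreement as the uncertainty of the species' shift — appropriate
  when the $k$ ENMs are seen as exchangeable draws from a space of
  defensible modelling choices rather than independent noisy replicates
  of one true value.
* **Variance of the mean** $V_i/k$: the squared standard error of
  $D_i$ as an average of $k$ replicates. This is the convention under
  which simulated replicate noise gives valid CI coverage, so the
  parameter-recovery machinery (`recovery_experiment()`,
  `sim_effects_table()`) defaults to it: with the raw variance, the
  model's assumed within-species variance overstates the actual sampling
  variance of $D_i$ by a factor of about $k$, and $T^2_s$ would absorb a
  compensating negative bias of roughly $(k-1)/k \cdot E[\sigma^2]$ —
  recovery of a known $T^2_s$ would fail by construction, telling us
  about the convention rather than the estimator.

## The toy ENM ensemble

Three fully specified models turn occurrence cells plus baseline/future
climate grids into range sizes: a bioclimatic envelope (presence iff
every layer is inside the $[q, 1-q]$ presence quantile envelope,
$q = 0.05$ by default) and two distance models (negative euclidean
distance in z-scored layer space, or Gower-style mean range-normalized
absolute difference, to the presence centroid). Continuous suitability
becomes presence/absence by the lowest-presence threshold — the minimum
suitability observed at a presence cell in the baseline — applied
unchanged to the future climate; standardization parameters and the
centroid always come from the baseline. Everything is deterministic given
its inputs, and identical baseline and future climates reproduce every
baseline prediction exactly ($D_{ij} = 0$ for all models: the pipeline
null). The ensemble exists to exercise the pipeline, not to emulate any
production ENM; constant layers are skipped with a warning, and a
single-presence envelope with $q > 0$ is rejected as degenerate.

## The synthetic-data generator

`simulate_effects()` draws exactly the data-generating process the model
assumes: a Yule tree (hand-written crown-conditioned pure-birth
simulator; expected height $(H_n - 1)/\lambda$, which the test suite
checks against 1,000 replicates), $u_p \sim MVN(0, T^2_p \mathbf{R})$,
$u_s \sim N(0, T^2_s)$, replicate noise $e_{ij} \sim N(0, \sigma_i^2)$
with $\sigma_i$ log-normal (median 15%, geometric SD 2, chosen so CI
widths spread over roughly an order of magnitude as in real forest
plots), and trait moderators with known coefficients. Defaults are the
study conditions the machinery targets: 500 species, 8 ENMs, true mean
shift −25%, $T^2_s = 500$, $T^2_p = 50$.

What passing tests on these data do **not** show: robustness to skewed
effect distributions (real range gains are long-tailed), to
mis-estimated $V_i$ (real $V_i$ comes from 8 correlated models, not
independent replicates), to tree misspecification, or to non-Brownian
phylogenetic signal. The generator validates the estimator under its own
assumptions; it does not validate the assumptions.

Parameter recovery at the default conditions (100 replicates) gives 95%
CI coverage for the mean of about 0.88–0.95 and recovers $T^2_s$ with
median error well under 10%. The mild undercoverage is a known property
of plug-in REML intervals here: in replicates where $\hat T^2_p$
collapses to the zero boundary, the phylogenetic contribution to
$\mathrm{Var}(\hat M)$ — which does not vanish with $n$, because deep
shared branches correlate all species — is dropped from the SE. We
verified these collapses are genuine global REML optima, not optimizer
failures.

## Problem sizes and runtimes

The test suite validates the optimizer against grid searches at $n = 6$,
against `metafor` at $n = 25$–$50$, and runs the full recovery experiment
at $n = 500 \times 8$ with 100 replicates (about a minute: one Cholesky
per likelihood evaluation, analytic gradients, one optimizer start from
the moment estimate). The acceptance script uses the same conditions with
a 50-replicate recovery. Property-style checks (scale invariance,
permutation invariance, $I^2$ additivity, determinism under seed) loop
over modest generated cases with fixed seeds.

## Known limitations

* A single tree is consumed as-is; consensus construction and taxonomic
  name matching happen upstream.
* The meta-regression requires complete traits (complete-case species
  subset, logged), and moderators are modelled linearly.
* No robust/cluster variance estimators; ML instead of REML only as a
  method switch; no model selection.
* $T^2$ SEs are delta-method approximations from the observed
  information; near the zero boundary they are reported as `NA`.
* Only three of a production ensemble's ENM families are represented in
  the toy ensemble; the meta-analytic layer is agnostic to how the
  projection table was produced.
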