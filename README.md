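# rangemeta

Meta-analysis of projected species range shifts from ensemble ecological
niche models (ENMs), with phylogenetic multilevel random effects.

## The problem

Ensemble forecasting of climate-driven range shifts produces, for every
species, as many projected range sizes as there are niche models — and the
models disagree. Treating each species' ensemble as one noisy estimate
turns the cross-species synthesis into a meta-analysis: species whose ENMs
agree carry more weight, species whose ENMs scatter carry less, and the
disagreement itself becomes a quantified component of the total variance.

For species *i* and niche model *j*, the effect size is the proportional
range shift

&nbsp;&nbsp;&nbsp;&nbsp;*D<sub>ij</sub>* = (*y<sub>ij</sub>* − *x<sub>ij</sub>*) / *x<sub>ij</sub>* × 100,

with *x* and *y* the baseline and future projected range sizes
(grid-cell counts). Averaging over the ensemble gives the per-species
effect *D<sub>i</sub>*; the cross-ENM variance *V<sub>i</sub>* measures its
uncertainty. These enter a phylogenetic multilevel random-effects model

&nbsp;&nbsp;&nbsp;&nbsp;*D<sub>i</sub>* = **x**<sub>i</sub>′**β** + *u<sub>s,i</sub>* + *u<sub>p,i</sub>* + *e<sub>i</sub>*,

where *u<sub>s</sub>* ~ N(0, *T*²<sub>s</sub>**I**) is unstructured
between-species heterogeneity, *u<sub>p</sub>* ~ N(0, *T*²<sub>p</sub>**R**)
is phylogenetically structured heterogeneity on the Brownian-motion
correlation **R** derived from the tree, and
*e<sub>i</sub>* ~ N(0, *V<sub>i</sub>*) carries the known within-species
variance. Variance components are estimated by REML; the intercept of the
null model is the weighted mean shift *M*, with weights
*W<sub>i</sub>* = 1/(*V<sub>i</sub>* + *T*²). Heterogeneity is summarized
by Cochran's *Q* and by the *I*² decomposition
*I*²<sub>t</sub> = *I*²<sub>s</sub> + *I*²<sub>p</sub>; trait
meta-regressions report a pseudo-*R*² (the proportional reduction in
*T*²).

The package also ships a small, fully specified toy ENM ensemble
(bioclimatic envelope + euclidean and Gower distance models with a
lowest-presence threshold) to produce projection tables end to end, and a
synthetic-data generator with known ground truth for validation.

## Worked example

```r
library(rangemeta)
set.seed(1)
cfg <- sim_config(n_species = 150, seed = 42)   # truth: mu = -25, T2s = 500, T2p = 50
sim <- simulate_effects(cfg)
eff <- sim_effects_table(sim)                   # D_i, V_i per species
fit <- rangeshift_meta(D ~ 1, data = eff, vi = V, R = sim$R)
print(fit)
```

```
Phylogenetic multilevel random-effects meta-analysis (REML)
n = 150 species; phylogenetic correlation supplied 

T2 (species):      686.9 (SE 96.95)
T2 (phylogenetic): 64.24 (SE 74.69)
I2 total 99.1% (species 90.6%, phylogenetic 8.5%)
Q = 12371.18, df = 149, p <2e-16

            estimate    se  ci_lb  ci_ub   stat      pval
(Intercept)      -30 3.716 -37.35 -22.66 -8.074 2.114e-13
```

The weighted mean shift is −30% (95% CI −37.4 to −22.7): on average these
simulated species are projected to lose about a third of their baseline
range, and the truth (−25) lies inside the interval. Nearly all of the
variance in shifts (I² = 99.1%) is real between-species heterogeneity
rather than ENM disagreement; only a small part of it (8.5 points) is
phylogenetically structured.

A trait meta-regression on the same fit:

```r
mr <- meta_regression(eff, sim$traits, R = sim$R,
                      moderators = c("clutch_size", "iucn_ordinal"))
coef_table(mr)
pseudo_r2(fit, mr)
```

```
             estimate   se  ci_lb  ci_ub   stat     pval
(Intercept)    -25.63 6.15 -37.78 -13.48 -4.167 5.24e-05
clutch_size     -1.39 1.61  -4.57   1.79 -0.865 3.88e-01
iucn_ordinal    -0.56 2.62  -5.74   4.62 -0.214 8.31e-01
pseudo-R2: 0
```

Neither trait predicts the shift here — correctly, since the generator's
true trait effects are zero — and the pseudo-*R*² is 0.

`species_effects()` builds the effect table from a real projection CSV
instead; `run_pipeline()` drives the whole analysis (effects → null fit →
meta-regression → class counts → forest table) from a YAML config, and
`inst/cli/rangemeta.R` wraps it for the shell.

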