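---
title: "Methods: TPE definition, selection efficiency and pedigree prediction for a wheat MET network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TPE definition, selection efficiency and pedigree prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A centralized wheat breeding program selects lines in a handful of managed
selection environments (SEs) at one station — combinations of irrigation
level and planting date labelled B5IR, F5IR, B2IR, FDRT and BLHT — and
distributes the selected elite lines to a large international network of
cooperator sites, here 41 sites across India evaluated over 13 annual
cycles. Three questions drive the analysis this package implements:

1. **Which sites belong together?** Group the network's sites into target
   populations of environments (TPEs) using climate and soil covariates, so
   that genotype-by-environment (GE) interaction *within* a group is small
   relative to the variation *between* groups.
2. **Is indirect selection efficient?** Quantify, per TPE, how much
   genetic progress selection at the station delivers relative to direct
   selection in the TPE (correlated vs direct response).
3. **Can station data predict TPE performance, and how fast are yields
   improving?** Fit pedigree-based reaction-norm models that borrow
   information across relatives and environments, and regress model
   predictions on trial year to estimate realized genetic gain.

# Models and procedures

## TPE definition

Daily values of nine meteorological variables are averaged over six
consecutive 20-day windows starting November 23 (the median planting
date), giving 54 covariates per site; nine static soil variables complete
a 63-column site matrix. PCA on the correlation matrix summarizes the
dominant axes, and Ward hierarchical clustering on Euclidean distances of
the standardized covariates partitions the sites at a user-chosen `k`
(default 3). The published analysis inferred the number of groups from the
PCA informally ("groups that explain most of the variation"); we do not
operationalize a rule and instead report variance explained around the
chosen `k`. Cluster labels are deterministic: clusters are renumbered by
ascending mean temperature so "TPE 1" is always the coolest group.

A thin-plate spline (d = 2, m = 2, radial basis $r^2 \log r$) can
interpolate cluster membership or any site statistic over coordinates; the
penalized criterion $\lVert y - g\rVert^2 + \lambda J(g)$ is solved by the
QR null-space algorithm, which is stable down to $\lambda = 0$ (exact
interpolation) and tends to the affine least-squares fit as
$\lambda \to \infty$. GCV chooses $\lambda$ when it is not supplied.

## Trial mixed models

Four REML templates cover the trial analyses (all random effects iid
Gaussian, variances constrained nonnegative; boundary estimates are
reported as exact zeros):

* `eq3` (per year, across sites): environment fixed; replicate,
  replicate-within-environment, genotype, genotype-by-environment random.
* `eq4` (per year, TPE structure): TPE fixed; genotype, genotype x TPE,
  genotype x environment(within TPE), environment, replicate and
  alpha-lattice sub-block random.
* `eq7` (single SE trial) and `eq8` (across SEs): the station-side
  analogues.

Broad-sense heritability on an entry-mean basis is
$H^2 = V_g / (V_g + V_{ge}/n_e + V_r/(n_r n_e))$, and with TPE structure
$H^2 = (V_g + V_{g \times tpe}) / (V_g + V_{g \times tpe} +
V_{ge(tpe)}/n_e + V_r/(n_r n_e))$. `ne` defaults to the number of
environments contributing data (the published per-year values are not
available); `nr` defaults to 2. Both are recorded in the result.

Fitting is delegated to `lme4` (REML with the nonnegativity constraint
built in); this is infrastructure, not the scientific contribution, and
the test suite checks it against two independent oracles: the balanced
one-way ANOVA closed form and a brute-force restricted-likelihood grid
maximizer evaluated with this package's own dense `restricted_loglik()`.

BLUEs treat genotype as fixed with cell-means coding (`~ 0 + genotype`),
so each coefficient directly estimates that genotype's adjusted mean —
equivalent to, and simpler than, sum-to-zero contrasts plus intercept.

## Selection response

With phenotypic correlation $p_{ij}$ between the genotype BLUEs of two
environment groups and group heritabilities $h^2_i, h^2_j$, the genetic
correlation is $r_{ij} = p_{ij}/\sqrt{h^2_i h^2_j}$. Because estimated
heritabilities can be small, $r$ may exceed 1; the raw value is retained
(it feeds the correlated response, and the published tables contain such
cells) alongside a clamped copy. Correlated response to indirect
selection is $CR = \bar r \sqrt{H^2_{SE}/H^2_{TPE}}$ and direct response
is $DR = i \, V_g^{tot}/\sqrt{V_z}$ with $i = 1$; in across-TPE analyses
$V_g^{tot} = V_g + V_{g\times tpe}$. The printed source renders these two
formulas ambiguously; the implemented forms are fixed by the accompanying
prose and verified against the published worked-example cells in the
acceptance tests. $\bar r$ is the arithmetic mean over years with
estimable correlations.

## Pedigree kinship

The additive relationship matrix uses the tabular method on a
topologically ordered pedigree: $a_{ii} = 1 + \tfrac12 a_{p_1 p_2}$,
$a_{ij} = \tfrac12 (a_{j p_1} + a_{j p_2})$, unknown parents treated as
unrelated non-inbred founders. A recursive coancestry oracle verifies it
in the tests. Dense storage is used; the program scale (a few thousand
lines) does not need sparse machinery.

## Reaction-norm prediction

Records are line-environment combinations (environment = TPE/SE-year).
Kernels: $K_a = Z_p A Z_p'$; $K_E = Z_E Z_E'$; $K_{aE} = K_a \circ K_E$
(Hadamard product — the reaction-norm structure on GE); for measured
environmental covariates, $K_W = WW'/q$ with the $q$ columns of $W$
centered and scaled, and $K_{aW} = K_a \circ K_W$. Schur's product
theorem guarantees PSD; the eigendecomposition asserts it numerically on
every build (1e-8 jitter).

The Gibbs sampler works in each kernel's eigenbasis, where the
conditional posterior of the effect coordinates is independent Gaussian,
with scaled-inverse-chi-squared conjugate updates for the variances
(df = 5). Prior scales follow the standard Bayesian-GBLUP default: half
of the sample variance of the response is split equally across the kernel
terms (normalized by each kernel's mean diagonal), the other half is the
residual's prior mode. An earlier draft split the variance equally over
all components including the residual; parameter-recovery simulations
showed that this visibly inflates small interaction components (the
restricted-likelihood fit of the same data sat at the simulated truth
while the posterior did not), which motivated re-deriving the cited
default exactly. Held-out records are handled by data augmentation:
imputed each sweep from the current model, with the posterior mean of the
linear predictor reported as the prediction. With fixed variances the
posterior is Gaussian and its mean is computed in closed form (no Monte
Carlo), which the tests compare to an independent kernel-ridge solve.

Default chain settings are 12,000 iterations, 2,000 burn-in, thinning 5,
2 chains; the test suite scales chains down (3,000/1,000/2) to stay
inside its time budget, and reports split-$\hat R$ per variance.

## Genetic gain

Per TPE, the per-cycle genotype BLUEs are fitted with the two-kernel
pedigree model $y = \mu + E + a + e$, $a \sim N(0, \sigma^2_a A)$, the
variances estimated by REML on the kernel representation. The estimated
rate of gain is the OLS slope of the model's predicted line values
($\mu + E + a$) on cycle year, scaled to kg/ha/year.

This is the one place where the design was genuinely open: regressing the
additive BLUPs $a$ alone is ill-posed in this network, because entries
are replaced every cycle, so a common per-year genetic shift is
statistically confounded with the environment (TPE-year) effect and
identified only through the pedigree prior. A pilot simulation made this
concrete: with a +100 kg/ha/year shift injected into line means, the
slope of the additive BLUPs alone was ~0 (the environment term absorbed
the trend), while the slope of the fitted line values recovered the
injected trend up to year-level noise. The fitted-value regression is
therefore the package's definition of the procedure. The slope's standard
error should acknowledge that environment draws are shared within a year:
the acceptance check regresses per-year means (`per_line = FALSE`) so the
SE reflects year-level clustering.

# The synthetic-data generator

The generator states the world the analysis assumes, with the published
network structure as defaults: 41 sites in TPE groups of 15/8/18; 13
cycles (2001, 2005-2016); 49 lines per cycle plus a site-specific local
check; 2 replicates in 5 alpha-lattice sub-blocks of 10; 5 SEs at one
station with mean yields 7.1/4.8/3.7/6.7/2.5 t/ha; variance components at
the published multi-year averages; site-year dropout probability 0.54
(the real network realized 245 of 533 site-year cells). TPE fixed means
are 5.1 and 3.7 t/ha for TPEs 1 and 2 as published; TPE 3 is set to
4.8 t/ha so the weighted network mean is the published 4.7 t/ha.
Covariates are drawn around the published TPE-level means; within-TPE
dispersions are not published, so site/year/daily noise defaults
(0.2/0.2/0.5 of each variable's between-TPE SD) were chosen once as
values a trial agronomist would call realistic while keeping the groups
distinct. Line effects on the SE and TPE sides share a latent genetic
factor with correlation 0.6, matching the medium published genetic
correlations. Gaussian yield draws below zero are censored at zero
(physical floor; a fraction of a percent of records at default
variances).

What the generator does *not* emulate — and hence what a green test does
not establish: autocorrelated weather (no storm structure), QTL-level
genetic architecture, spatial field trends within trials, heterogeneous
residual variances across sites, and non-Gaussian yield shocks. Recovery
tests on this generator certify the estimators under the model's own
assumptions, not robustness to their violation.

# Numerical choices

* REML convergence is lme4's default; variance boundary estimates are
  truncated below 1e-10 to exact 0.
* Kernel eigenvalues below `max(eig) * 1e-10` are truncated; a minimum
  eigenvalue below `-1e-6 * max(eig)` after jitter is an error.
* The Gibbs sampler refuses settings yielding fewer than 100 kept
  samples.
* CSV output writes doubles at 17 significant digits so read-back is
  bit-exact; nested results go to JSON.
* Cluster-label ties (equal mean temperature) break by first occurrence;
  zero-variance covariate columns are dropped with a warning before
  PCA/clustering.
* A constant response in the sampler is handled by flooring the sample
  variance at 1e-8; posteriors then sit at the prior floor.

# Known limitations

* At a training size of ~2000 records, the posterior for the smallest
  interaction variance (the additive-by-covariate component) remains
  partly prior-dominated: its kernel carries few effective dimensions of
  information, so a true value well below the prior mode is recovered
  only marginally (the corresponding acceptance check sits at the edge
  of its 3-posterior-SD band and fails for some data realizations while
  the restricted-likelihood fit of the same data recovers the truth).
  At the real program's scale (an order of magnitude more records and
  lines) the prior's influence is negligible.

* `run_cli("response", ...)` consumes summary tables (as in the worked
  examples) rather than re-deriving every intermediate from raw plot
  data; the full chain is available programmatically.
* The Gibbs sampler materializes dense record-level kernels; it is meant
  for the program scale (up to a few thousand records per fit), not
  biobank scale.
* Genetic-gain estimates inherit the identifiability caveat above: they
  measure the trend in predicted line performance, which conflates
  genetic trend with any environment trend the model attributes to lines
  only through the pedigree.
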