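---
title: "Methods: models, estimators and design choices in stomevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in stomevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stomevol)
```

`stomevol` implements a comparative-phylogenetics workflow for asking
whether habitat shapes stomatal (guard-cell) size independently of
genome size. This vignette is the package's account of the underlying
models, the estimators and their numerical details, the synthetic data
the test suite rests on, and the design decisions that were genuinely
open.

## The data and their hierarchy

The analysis currency is a per-individual trait table: species, genus,
a deep-clade flag (a "persoonioid"-like heavy-genome clade versus the
rest), a binary vegetation type (open vegetation vs closed forest),
guard-cell length (μm), holoploid genome size (2C, pg), dry-quarter
precipitation (mm), and a replicate id. Genome size, guard-cell length
and precipitation are right-skewed, so every model works on the log10
scale. Replicates are averaged **after** the log transform (the modeled
quantity is log guard-cell length, and averaging on the analysis scale
keeps it Gaussian); the ordering mattered little in practice but had to
be fixed somewhere, and this is the package's choice.

Two views of the data feed two analysis levels:

* **High level** (ancient divergences): one terminal per genus on a
  dated tree, species means of replicates, used for signal statistics
  and PGLS.
* **Low level** (recent divergences): only genera with ≥ 2 species,
  replicate records retained, used for nested variance components and
  the genus bootstrap. Known neopolyploids are excluded here, since
  whole-genome multiplication is a different process from the gradual
  genome-size evolution at issue.

Species are matched to tree tips exactly by name first, then by genus
(assuming genus monophyly); fallbacks are reported. Dated trees must be
ultrametric within a relative tolerance of `1e-6` on root-to-tip
distances; a failure warns rather than errors because published node
ages are usually rounded. When a terminal has to be grafted under a
dated node whose exact divergence is unknown, the default places it at
the midpoint between that node's age and the present — the plain
reading of "interpolating between the node and the terminals" — and an
explicit age override is exposed because the true interpolation rule is
not knowable from a midpoint description.

## Phylogenetic signal

For a trait $y$ on a tree with Brownian covariance matrix $V$ (entry
$(i,j)$ = shared root-to-MRCA path length, Myr):

* **Blomberg's K** compares the observed ratio of the ordinary to the
  phylogenetic mean squared error with its Brownian expectation,
  $K = \frac{MSE_0 / MSE}{[\mathrm{tr}(V) - n/(\mathbf{1}'V^{-1}\mathbf{1})]/(n-1)}$,
  with $\hat a = (\mathbf{1}'V^{-1}\mathbf{1})^{-1}\mathbf{1}'V^{-1}y$
  the GLS mean. $K = 1$ under Brownian motion on the given tree; on a
  star tree $K = 1$ identically, which the tests exploit. The p-value
  permutes trait values across tips and counts permutations whose
  phylogenetic MSE is at most the observed one, with a `+1` correction.
  The default is 999 permutations (seedable); the source analyses do
  not state a count, and 999 makes the smallest attainable p-value
  0.001.
* **Pagel's λ** multiplies the off-diagonal of $V$; $\hat\lambda$
  maximizes the profile Gaussian likelihood (GLS mean and
  $\hat\sigma^2 = RSS_V/n$ profiled out) over $[0, 1]$ — 1 is the
  largest value keeping $V(\lambda)$ positive definite on ultrametric
  trees, and if a proposal is numerically non-PD the search bound
  shrinks instead of failing. The p-value is a likelihood-ratio test
  against $\lambda = 0$ on $\chi^2(1)$ **without** a boundary
  correction, matching the convention of the widely used
  implementations; this is conservative when the truth sits on the
  $\lambda = 0$ boundary.

Ancestral states under Brownian motion are the joint-ML (GLS)
estimates $\hat a_k = \hat a_{root} + C_k V^{-1}(y - \hat a_{root}
\mathbf{1})$, with $C_k$ the shared path lengths between node $k$ and
each tip. They are affine-equivariant and exact (no optimization); the
tests confirm equality with brute-force maximization of the joint
likelihood over all node states. Reconstructions of this kind are
biased under directional evolution, which is an interpretive caveat,
not something the estimator can fix.

## PGLS and model competition

The regression model is $y = X\beta + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2 V(\lambda))$. For fixed $\lambda$ the
estimates are the GLS formulas; $\log L = -\tfrac12[n\log(2\pi\hat\sigma^2)
+ \log|V(\lambda)| + n]$ with $\hat\sigma^2 = RSS_V/n$, and $\lambda$
maximizes this profile on $[0,1]$ (Brent search, tolerance `1e-8`,
boundary candidates re-checked). Categorical predictors are
treatment-coded with the alphabetically first level as reference;
fits, residuals and AIC are invariant to that choice, and the tests
assert it. Coefficient covariance uses the residual-df variance
estimate $RSS_V/(n-p)$, so the marginal F of a one-column predictor
equals its squared t.

Per-predictor tests are **marginal** (drop-one) F-tests with λ reused
from the full fit: the reduced model drops all of a term's columns,
$F = \frac{(RSS_{red} - RSS_{full})/q}{RSS_{full}/(n - p_{full})}$.
Marginal rather than sequential tests were chosen for
order-independence; dropping a main effect while its interaction stays
is refused. Model competition fits every candidate — by default all
subsets of {log genome size, vegetation, log dry-quarter precipitation}
plus the vegetation × genome interaction — re-estimating λ per
candidate (the behaviour of the reference GLS implementations), with
$AIC = -2\log L + 2k$ where $k$ counts the coefficients plus $\sigma^2$
plus λ when estimated. Exact AIC ties rank the smaller model first.

One property of this procedure is worth stating plainly: AIC admits a
superfluous one-parameter extension of the true model whenever the
extension's likelihood-ratio gain exceeds 2, which happens with
probability $P(\chi^2_1 > 2) \approx 0.16$ per null competitor (a bit
more at small $n$). With two null supersets in the candidate set (the
precipitation model and the interaction model), the true additive
model is the *strict* AIC minimum in only ~63–71% of simulated studies
at $n = 50$, no matter how strong the true effects are. It is, however,
essentially always within ΔAIC < 2 of the top. Selection-consistency
expectations above that ceiling cannot be met by a faithful AIC
implementation, and the package does not inflate them.

## Nested variance components

The low-level model is $y_{ijk} = \mu + g_i + s_{ij} + e_{ijk}$ with
independent normal effects for genus, species-within-genus and
replicate. Estimation is **ML** (not REML) to match the "maximum
likelihood analysis" framing of the workflow; note the ML genus
variance carries the usual $(G-1)/G$ shrinkage, and REML is available
behind a flag for sensitivity. The likelihood is evaluated from
per-species sufficient statistics (replicate mean, within-SS, count):
within-species contrasts give the $\sigma^2_e$ part, species means form
per-genus blocks $\sigma^2_g J + \mathrm{diag}(\sigma^2_s +
\sigma^2_e/n_{ij})$ inverted by Sherman–Morrison, and $\mu$ is profiled
by GLS. Optimization runs on log-variances (Nelder–Mead with a
projection at $10^{-12}\times$ the total variance, restarted twice with
shrinking steps) — a boundary estimate is reported as 0 and flagged.
This core is in C++ because the bootstrap below refits it on the order
of a million times. Standard errors come from the inverse observed
information (central-difference Hessian of the profile likelihood on
the variance scale); components at the zero boundary get `NA` SEs. The
tests verify exact agreement of the likelihood and estimates with
`lme4` (ML and REML) and with an independent EM algorithm.

## The genus bootstrap

The directional claim — guard-cell length carries relatively more
within-genus variation than genome size — is tested on the ratio
$\rho_t = \hat\sigma^2_{species}(t) / \hat\sigma^2_{genus}(t)$ and the
statistic $D = \rho_A - \rho_B$. "Resampling genera with substitution"
is read as a bootstrap of whole genera with replacement: the genus is
the exchangeable unit of the claim, each drawn genus keeps its
species/replicate records intact, the **same** drawn genus list is
applied to both traits, and duplicated genera are relabeled as distinct
units. The one-sided p-value is $(1 + \#\{D_{rep} \le 0\})/(n_{reps} +
1)$, never exactly zero. A resample whose genus variance hits the zero
boundary gets $\rho = +\infty$ (its within-genus share is total
relative to a nil among-genus component); D then takes its sign from
the other trait, replicates degenerate in both traits score $D = 0$,
and all such replicates are counted in a diagnostics field. The
statistic is a difference of ratios rather than a ratio of ratios so
that $D$ is antisymmetric under swapping the traits, which the tests
assert along with scale invariance and seed-stability of p. Under an
equal-ratio null at the 13-genus scale the measured type-I error is
0.062 at $\alpha = 0.05$, and power against a strong within-genus
guard-cell excess ($\rho_A = 2.6$ vs $\rho_B = 0.06$) is 0.96.

## Flow cytometry

Sample 2C = reference 2C × (sample peak mean / reference peak mean) —
the standard internal-standard ratio — with 1C = 2C/2 reported
alongside. Replicate-run repeatability is the pooled SD of log10 2C,
weighting each sample by its degrees of freedom, and its percent-scale
equivalent uses $(10^{SD} - 1)\times 100$; for small SD this is
indistinguishable from $\ln(10)\,SD$, and the formula choice is the
package's own since only the rounded percentage is conventionally
quoted.

## What the synthetic data emulate — and what they do not

`simulate_study()` generates the design the analyses expect: a dated
pure-birth tree over 48 genera (root age 95 Myr, the approximate crown
age of the family-scale radiations in view), 67 species with 13
multi-species genera (6 × 3 + 7 × 2 species), two replicate plants per
species for guard cells and two cytometry runs per species for genome
size. Log genome size evolves by Brownian motion (among-genus SD 0.35
on log10 2C around a mean of 0.7, i.e. ~5 pg) with a +1.0 offset on
the smallest ~4-genus clade, emulating a heavy-genome subfamily;
within-genus species SD is 0.01 and run-level SD 0.0194, the published
repeatability of careful replicate cytometry. Guard-cell length follows
$\log_{10}GCL = 1.60 + 0.25(\log_{10}2C - 0.7) + 0.16\,[\text{open}] +
u_{phylo} + s_{species} + e_{rep}$ with phylogenetic residual SD 0.04,
species-level SD 0.14 and replicate SD 0.04. These defaults were set
once, from the printed magnitudes of the system being emulated (guard
cells ~19–72 μm, 1C ~0.5–30 pg, a genus-dominated genome partition
around 99% and a species-dominated guard-cell partition around
25/70/5), and are sanity bounds, not fitted values.

What the generator deliberately does not model: within-species genome
variation beyond measurement noise, chromosome-number evolution,
correlated evolution of vegetation with the traits (vegetation is iid
per species by default; a one-rate two-state Markov switch along the
tree is available behind `veg_clumped = TRUE`, since habitat is clearly
phylogenetically clumped in real clades, but the rate of that switch is
our choice, not an estimate), plasticity structure within species, or
measurement error in precipitation. Passing tests therefore demonstrate
that the estimators recover the assumed generating processes — not that
real data satisfy those assumptions.

## Numerical choices and degenerate inputs

* Ultrametricity tolerance `1e-6` (relative); violations warn.
* V(λ) positive-semidefiniteness accepted down to eigenvalues
  $\ge -10^{-9}\lambda_{max}$; Cholesky failures during λ search shrink
  the bound.
* λ optimization tolerance `1e-8`; grid-search cross-checks in the
  tests use a step of `1e-4`.
* Variance components floor at $10^{-12}\times$ total variance;
  estimates below $10^{-9}\times$ total variance are reported as 0 and
  flagged as boundary.
* Constant traits are errors for K, λ and the variance components (the
  statistics are undefined), as are single-genus tables.
* AIC ties: fewer parameters first, then the model label.

## Problem sizes in the test suite

The statistical suites run at sizes chosen to make sampling error small
relative to the asserted bands while keeping a single-CPU run short:
500 Brownian replicates for the K calibration and 500 permutations-test
replicates for its size; 200 replicates each for λ recovery (100 tips)
and model selection (50 tips); 100 replicates for variance-component
recovery (50 genera × 3 species × 2 replicates); and 500 × 999 null
plus 200 × 999 strong-effect replicates for the genus bootstrap at the
13-genus design of the low-level data. The full suite completes in a
few minutes.

## Known limitations

* The λ transform is the only covariance model; no OU or early-burst
  alternatives, and no non-Gaussian responses.
* The permutation and LR p-values for signal are unconditional on the
  tree; tree uncertainty is outside scope.
* ML variance components are biased downward at the genus level for
  small numbers of genera (use the REML flag to gauge the effect).
* The genus bootstrap is mildly anticonservative at 13 genera (measured
  size 0.062 at nominal 0.05); with so few exchangeable units that is
  expected, and conclusions resting on p-values near the threshold
  deserve caution.
* Coefficient-level reproduction of published analyses requires the
  underlying specimen tables and tree; the package reproduces the
  procedures, not any specific dataset.
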