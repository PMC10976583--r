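---
title: "Methods: comparative volumetrics and phylogenetics of the red nucleus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative volumetrics and phylogenetics of the red nucleus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rubrovol` implements a complete comparative analysis of a brain
region's volume across species — here the primate red nucleus (RN) and
its magnocellular (RNm) and parvocellular (RNp) subdivisions. This
vignette is the package's own account of the models it fits, the
parameters that matter, the numerical choices made, and what its tests
do and do not establish.

```{r setup, eval = FALSE}
library(rubrovol)
```

## From sections to volumes

Histological volumes are Cavalieri estimates: the structure is
delineated on a systematic subsample of serial sections and the volume
is the sum of delineated areas times the spacing between measured
sections,

$$\hat V = s \sum_i A_i \times k,$$

where $s$ is the spacing (mm), $A_i$ the areas (mm²), and $k$ the
shrinkage factor — the ratio of estimated fresh volume to
post-processing volume — which restores fresh-tissue scale. The
estimator is exact in the limit $s \to 0$ and its error on smooth solids
shrinks quadratically with spacing when sections are placed at a
systematic uniform offset; `ellipsoid_sections()` exists so that this
convergence can be checked against an analytic volume (the tests verify
agreement within 2% at 0.1 mm spacing on a 2×1×1 mm ellipsoid).

Fresh brain volumes come from fresh weights via a density constant,
default **1.032 g/cm³**. The default is validated in the test suite by
an internal consistency check: the mean fresh weight of the ten mapped
human specimens in the packaged specimen table, divided by 1.032,
reproduces the human brain volume in the packaged species table to
better than 0.1%. The constant is an argument, not a hard-coded value,
because the weight-to-volume conversion is a literature convention.

## Summaries and conventions

`rn_species_summary()` computes bilateral sums, relative volumes
(% of brain volume), the RNm/RNp ratio, its log10, and the relative
difference (RNp − RNm as % of brain volume). Two aggregation conventions
exist at group level, and both are exposed because neither is uniquely
"right":

* **Relative volumes** are averaged across species within a group
  (mean ± SEM of the per-species percentages). This is the convention
  under which the packaged table reproduces the published group
  percentages.
* **Fold ratios** between the subdivisions default to the ratio of
  group-mean bilateral volumes (`ratio_method = "group_mean"`), which
  reproduces the published between-group fold differences; the mean of
  per-species ratios is available as `"species_mean"`. The group-level
  relative difference follows the same switch.

Percentages are kept at full precision internally; rounding to the
printed precision (3 decimals for percentages, 1 for mm³) is left to
display code.

**Asymmetry tests.** Left/right comparisons use a paired test chosen by
a normality gate on the paired differences at the 0.05 level: paired
t-test if normality is not rejected, Wilcoxon signed-rank otherwise.
The gate is the Anderson–Darling test where its null distribution is
tabulated (n ≥ 8) and Shapiro–Wilk for 3–7 pairs, since
Anderson–Darling is undefined below eight observations and the species
groups here have as few as three. An all-zero difference vector makes
the signed-rank statistic undefined; the function returns p = 1 with a
warning rather than erroring, reading "no evidence of asymmetry" off a
degenerate input. Monte-Carlo checks in the suite confirm the type-I
error is ≈ 0.05 and power against a 2-SD paired shift at n = 10 is
high.

## The phylogeny

Comparative data are not independent; every model here conditions on a
tree. Trees are `ape::phylo` objects; `read_newick()` adds validation
(single root, branch lengths present and non-negative, unique non-empty
tip labels, parse errors reported with a character offset) and
`bm_covariance()` builds the Brownian-motion covariance — shared
root-to-MRCA path lengths — with polytomies treated as hard.

The dated tree used in the original study came from an external service
and cannot be redistributed, so the package ships a **surrogate
chronogram**: a fixed topology (prosimians sister to all simians;
platyrrhines sister to catarrhines; cercopithecids sister to hominoids;
humans nested within the hominoids next to *Pan*) with node ages set
once from round consensus values in the primate literature (root 74 Ma,
platyrrhine–catarrhine 43 Ma, cercopithecid–hominoid 31 Ma,
human–chimpanzee 7 Ma, and so on; see `rn_node_ages()`). Ages are a
configurable argument. Two consequences are worth stating plainly:

* All statistics in the package are invariant to a global rescaling of
  the tree (tested), so the absolute time scale is immaterial.
* Quantities that depend on the exact branch-length proportions —
  F statistics, bootstrap percentages, effect sizes — will differ
  between the surrogate and any other dated tree. The package therefore
  treats published values of such quantities as qualitative anchors
  (same shift locations, same test decisions), not numeric targets, and
  the test suite is written accordingly.

Tip labels use underscores for spaces (`species_label()`), and the
species spellings follow the packaged trait table exactly so fixture
and tree always match.

## pGLS allometry

Scaling is modelled on log10 axes: $y = \beta_0 + \beta_1 x$ with
$x = \log_{10}$ brain volume (mm³) and $y = \log_{10}$ region volume
(mm³), errors distributed $N(0, \sigma^2 C)$ with $C$ the BM covariance.
`pgls_fit()` computes the GLS estimator
$(X^\top C^{-1} X)^{-1} X^\top C^{-1} y$ via Cholesky whitening and
estimates $\sigma^2 = r^\top C^{-1} r / (n - 2)$. With $C \propto I$
(a star phylogeny) the fit is exactly OLS, which the tests verify to
1e-10, alongside a brute-force matrix-inversion oracle and an
independent GLS implementation. Species means are the analysis unit —
one tip per species. Log base 10 is used throughout. A Pagel's-λ
argument exists for sensitivity analyses but defaults to 1 (plain BM
pGLS); no covariance transform is applied by default.

**Prediction intervals.** The per-species deviation flags use
leave-one-out phylogenetic prediction: species *i*'s interval is
centred on the regression value plus the residual predicted from all
other species through the phylogenetic covariance (a kriging/BLUP
step), with the conditional variance
$\sigma^2 (C_{ii} - c_i^\top C_{-i}^{-1} c_i)$ plus propagated
coefficient uncertainty, and Student-t quantiles on $n - 2$ df. The
marginal alternative (variance $\sigma^2 C_{ii}$) was deliberately not
used for flagging: when a single species is displaced, the inflated
$\hat\sigma^2$ widens marginal intervals enough to mask the very
outlier being sought, whereas the conditional interval — which asks
"is this species where its relatives and the allometry say it should
be?" — retains power (the suite verifies ≥ 95% detection of a 5-SD
displaced tip). On a star tree the two coincide.

## Multi-regime OU shift detection

Deviations from allometry are modelled as an Ornstein–Uhlenbeck process
on the tree,

$$dX(t) = \alpha\,[\theta - X(t)]\,dt + \sigma\,dB(t),$$

with a single $\alpha$ (pull toward the optimum) and $\sigma^2$
(stochastic variance) shared across the tree and an optimum $\theta$
that may shift on designated edges. A shift applies from the beginning
of its edge and paints the whole subtree below, nearest shift winning.
The root state sits at the ancestral optimum (stationarity convention,
the common choice; configurable in principle via the mean construction).
Tip expectations weight the optima along each root-to-tip path by the OU
decay factors, and the covariance between tips $i, j$ with shared time
$t_{ij}$ and patristic distance $d_{ij}$ is
$\frac{\sigma^2}{2\alpha}(1 - e^{-2\alpha t_{ij}})\,e^{-\alpha d_{ij}}$,
implemented in a form continuous at $\alpha = 0$ where it equals the BM
covariance $\sigma^2 t_{ij}$. Non-ultrametric trees are rejected — the
stationary-OU covariance used here assumes contemporaneous tips — which
is a documented limitation, not an oversight.

**Fitting.** For a fixed shift set, $\theta$ and $\sigma^2$ are profiled
analytically at each $\alpha$ (GLS on the regime design matrix;
rank-deficient regimes collapse to the base optimum) and $\alpha$ is
maximised on a log-spaced grid from 0.01 to 50 per unit tree depth
followed by a local search. **Search.** The shift configuration is
found by exhaustive scoring of all single edges, extended greedily
(forward selection) up to `max_shifts`, under an information criterion.
The default `pBIC` is BIC plus a placement-multiplicity term
$2\log\binom{E}{K}$ ($E$ edges, $K$ shifts), penalising the size of the
searched model space; plain BIC and AICc are available. In practice the
multiplicity term matters: on the packaged RNp data plain BIC happily
selects poorly identified tip shifts with absurd optima, while pBIC
selects none. Ties break toward fewer shifts, then toward the edge
closer to the root. The search never returns a configuration scoring
worse than the zero-shift model, and recovery simulations in the suite
confirm ≥ 90% recovery of a planted shift of 10 stationary SDs on
20-tip trees.

**Uncertainty.** `bootstrap_support()` is a parametric bootstrap:
simulate from the fitted model, rerun the search, report the percentage
of replicates selecting each edge (default 100 replicates, seeded).
`snr_effect_size()` reports, per shift, $|\Delta\theta|$ divided by the
stationary SD $\sqrt{\sigma^2 / 2\alpha}$ and scaled by the regime
balance factor $\sqrt{n_r(n - n_r)/n}$ — a signal-to-noise measure
where values ≫ 1 indicate a shift large relative to the trait's
stationary fluctuation. This is a clearly-labelled surrogate statistic:
the output tags it `fallback`, and it is anchored at zero, linear in
$|\Delta\theta|$, and qualitatively comparable to (not numerically
interchangeable with) published signal-to-noise effect sizes.

**Which residuals to analyze.** `run_rn_analysis()` feeds the shift
search the log10 *relative* volume ($\log_{10}$ region − $\log_{10}$
brain) by default, with one-grade pGLS residuals as an option. The
reason is statistical, and visible in the packaged data: when a deep
clade carries a genuine grade shift *and* the extreme predictor values
(hominoids have both the reduced RNm and the largest brains), the
one-grade pGLS tilts its slope toward the shifted clade — for RNm the
fitted slope drops to ≈ 0.2 against ≈ 1.05 for RNp — absorbing the
grade difference into the line and erasing it from the residuals. The
relative-volume transform imposes the proportionality benchmark instead
of estimating it from contaminated data, and under it the RNm shift on
the hominoid stem is detected with near-complete bootstrap support
while RNp yields no shift. Users who prefer the fitted-slope residual
can set `residual_type = "pgls"`.

## Phylogenetic ANCOVA

`grade_test()` turns a shift hypothesis into a confirmatory test:
nested GLS regressions (common versus group-specific intercepts and/or
slopes) compared in the whitened metric,

$$F = \frac{(RSS_0 - RSS_1)/\Delta p}{RSS_1/(n - p_1)},$$

with the standard nested-model degrees of freedom and p-values from the
F distribution. With identity covariance this is ordinary ANCOVA, and
the tests verify exact agreement with `anova()` on `lm` fits as well as
with a brute-force GLS oracle. Group factors use treatment contrasts
with the largest group as baseline; F is invariant to that choice
(tested). Degenerate perfection — both models fitting exactly — returns
F = 0 rather than 0/0. Under the null with BM noise and the correct
covariance, simulated p-values are uniform (KS-checked). Power against
a clade-wide intercept shift depends strongly on the depth of the
clade's stem branch, because a grade shift on a deep clade is partly
confounded with ordinary Brownian drift along that stem: on the
surrogate chronogram with the hominoid clade shifted, Monte-Carlo power
at 2 residual SDs is ≈ 0.75 and at 3 SDs ≈ 0.99. No multiplicity
correction is applied across responses — left and right sides are
analyzed, and reported, as independent confirmatory tests.

## Ancestral state estimation

`ase_bm()` computes the maximum-likelihood (equivalently GLS) nodal
estimates under single-rate BM by solving the inverse-branch-length
weighted-mean system — each internal node is the harmonic-weighted
average of its neighbours — which keeps every estimate inside the range
of the tip values. `ase_mvbm()` relaxes the single-rate assumption with
a multiple-variance scheme: alternate (i) BM estimation on rate-scaled
branch lengths and (ii) rate-scalar updates from the squared change per
unit original length along each branch, normalised to mean 1, with a
geometric damping step and a 1e-6 floor to keep the iteration stable
and the system well-posed, until nodal estimates move < `tol`
(default 1e-6, `max_iter` 100; non-convergence is flagged, not hidden).
Zero-length branches receive a pseudo-length of 1e-8 × tree depth with
a warning. With all rate scalars at 1 the scheme is exactly `ase_bm()`;
rate-recovery simulations confirm that a clade evolving 10× faster gets
systematically larger rate scalars. Nodal point estimates under any of
these models carry high inherent uncertainty: every report and print
method states that they are for visualizing trends through time, not
for quantitative inference.

## Morphospace clustering

`rn_features()` places each species at
$(x, y) = (|RNp - RNm| / BV \times 100,\ \log_{10}(RNm/RNp))$: the
y-axis carries direction (positive = RNm larger; zero = equal; $10^{|y|}$
is the fold difference) and the x-axis the size of the imbalance
relative to the brain. A signed-x variant exists. `kmeans2()` runs
k-means with k = 2 on the **raw** axes (no standardization by default,
matching how such morphospaces are usually plotted; `standardize`
available), best of `n_init = 50` seeded restarts. Labels are
arbitrary: all membership comparisons in the package and its tests use
partition equality. For n ≤ 8 the tests verify the WCSS against
exhaustive enumeration of all two-partitions. On the packaged table the
two clusters are exactly {humans + non-human apes} versus everyone
else, robustly across seeds, because the hominoid fold-imbalance
(y ≤ −1.2) is far from every other species (y ≥ −0.4).

`pearson_cor()` supports the companion analysis of RN scaling against
cerebellar volume; the external cerebellar volumes themselves are not
bundled (they are literature data), so that analysis runs only when the
user supplies them.

## Synthetic data

`simulate_bm()` and `simulate_ou()` draw tip vectors by exact
multivariate-Gaussian sampling from the model mean and covariance — no
Euler path discretization — so simulated data match the likelihoods
being tested exactly; both are bit-reproducible given a seed and the
OU simulator's marginals match the closed-form moments (tested).
`make_allometric_table()` assembles a full drop-in trait table: log10
brain volume evolves by BM (default σ² = 0.01 per Ma from a root of
~20 cm³, spanning roughly the observed 2.8–1236 cm³ range on the
surrogate tree), each region follows
$\log_{10} V = b_0(\text{group}) + b_1 \log_{10} BV + \varepsilon$ with
phylogenetically structured residuals (BM, default SD ≈ 0.14 at the
tips), slope 0.95, intercepts −2.6 (RNp) and −2.9 (RNm) giving relative
volumes of the order 0.01–0.1%, an optional grade shift (default −1.5
log units ≈ 30-fold, the order of magnitude separating hominoid RNm
from the rest) painted on designated edges, and left/right splitting
with log-normal jitter (SD 0.02, i.e. ±5% asymmetry, consistent with
the near-symmetric measured volumes). These defaults emulate the
statistical structure of the study data — power-law scaling,
clade-level grade shift, phylogenetic residuals, mild asymmetry. They
do **not** emulate measurement error from delineation, specimen-level
variation within species, shrinkage misestimation, or non-Gaussian
trait evolution; a passing end-to-end simulation therefore shows the
methods work under their own assumptions, not that real histological
data satisfy those assumptions.

## Problem sizes and reproducibility

The shipped analyses and tests use the 20-species table, trees of 8–100
tips, 100-replicate parametric bootstraps and recovery simulations,
200–500-replicate power and calibration runs, and a 1000-replicate null
for p-value uniformity — sizes chosen so the full suite and the
reproduction script each complete in minutes on a single core while
keeping Monte-Carlo error well below the margins being asserted. Every
stochastic function takes an explicit seed, simulation helpers restore
the caller's RNG state, and `run_rn_analysis()` derives per-response
seeds deterministically from its single seed, so identical inputs give
byte-identical numeric output.

## Known limitations

* The OU machinery requires ultrametric trees; fossil tips are out of
  scope.
* One $\alpha$ and $\sigma^2$ are shared across regimes; no multi-trait
  OU, no measurement-error model, no reversible-jump search.
* The pBIC placement penalty is a documented in-package construction,
  equivalent in spirit but not in detail to penalties in dedicated
  shift-detection packages; agreement is at the level of selected shift
  locations under strong signal (validated by simulation), not of
  criterion values.
* The mvBM rate-update scheme is likewise a documented iterative
  construction validated by its collapse-to-BM and rate-recovery
  properties, not a reimplementation of any specific published
  algorithm.
* Group-level inference treats the species means in the trait table as
  exact; specimen counts are carried but within-species variance is not
  modelled (for most non-human species n = 1 makes this unavoidable).
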