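---
title: "Comparing ontogenetic allometric trajectories across species"
author: "ontotraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing ontogenetic allometric trajectories across species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontotraj)
```

## The model

Within a species, shape changes with size as an animal grows. `ontotraj`
represents this as a linear ontogenetic allometric trajectory in size–shape
space: for species $i$ with shape vector $y \in \mathbb{R}^q$ and log size
$s$,

$$ y = a_i + \beta_i s + \varepsilon, \qquad
   \varepsilon \sim \mathcal{N}(0, \sigma^2 I_q). $$

The intercept vector $a_i$, the slope vector $\beta_i$ (the *direction* of
ontogenetic change), and the trajectory length
$L_i = \lVert \hat y_i(s_{\max,i}) - \hat y_i(s_{\min,i}) \rVert$ (the
*magnitude* of change between the smallest juvenile and the largest adult a
species actually reaches) are the attributes every downstream analysis
works with. Trajectory endpoints always use each species' own observed size
range: a truncated trajectory is a real biological signal (e.g. heterochrony
by ontogenetic scaling), not a nuisance.

Shape itself comes from one of two routes:

* **Linear measurements** become log-shape ratios: size is the natural log
  of the geometric mean of all measurements (body and limb tables pooled
  when a specimen appears in both, so the two datasets share one size
  axis), and each trait is divided by that geometric mean and
  log-transformed. Natural logs are used wherever a log appears; shape
  ratios are base-invariant up to scale, but one convention has to be fixed
  for reported attribute values.
* **2D landmark configurations** are superimposed by generalized Procrustes
  analysis (GPA), semilandmarks slide along tangents to minimize
  thin-plate-spline bending energy, and object symmetry is removed by
  averaging each configuration with its reflected, relabelled, re-aligned
  copy. Size is log centroid size. Analyses operate on the aligned
  coordinates directly, without a further tangent-space projection, which
  is the default behaviour of the field's standard toolchain for
  small-variation data sets.

Before any interspecific comparison, a sexual-dimorphism filter runs a
distance-based ANOVA of shape on sex within each species sampled for both
sexes and discards females where sex has a significant effect, reflecting
the male-biased sampling typical of museum series.

## Inference by residual randomization

All linear-model tests use distance-based (trace of cross-product) sums of
squares, so they remain defined when shape has more variables than
specimens have degrees of freedom. Null distributions come from residual
randomization: rows of the reduced model's residuals are permuted, added
back to the reduced-model fits, and the statistic recomputed. The observed
arrangement counts as one permutation (the add-one rule), so p-values are
never exactly zero; the convention is fixed here because the permutation
literature leaves it implicit. Each analysis derives its own child seed
from a single master seed (`child_seed()`), making results independent of
the order analyses run in.

The battery is:

* **Isometry test** (per species): shape ~ size against the intercept-only
  model. Non-significance labels the species isometric.
* **HOST** (homogeneity of slopes): `shape ~ size + species` against
  `shape ~ size * species`; the interaction F tests whether species need
  unique allometries.
* **Pairwise comparisons** of trajectory angles (degrees between full
  $q$-dimensional slope vectors, never PC-reduced) and lengths, with nulls
  from residual randomization of the common-slope model. Because every
  pairwise statistic is computed from the same permuted residuals, these
  p-values are reported unadjusted; all other pairwise families
  (intercepts, adult-shape distances) are Benjamini–Hochberg adjusted.
* **Intercept test** for slope-homogeneous pairs: Euclidean distance
  between intercept vectors under a common slope, permuting specimen
  species labels. "Common slope" is operationalized as unadjusted angle
  p ≥ 0.05.
* **Hierarchical partitioning** of pairwise adult disparity on the three
  attribute contrasts (angle, |ΔL|, intercept distance), by exact
  enumeration of all predictor subsets. We report independent effects as a
  share of their sum; the supporting identity — and the one tested — is
  that independent effects sum exactly to the full-model $R^2$. (The
  sometimes-quoted "independent + joint sums to the full $R^2$" is not an
  identity of this decomposition; joint effects are defined as each
  predictor's single-variable $R^2$ minus its independent effect.)

## Heterochrony

Two parallel decision paths classify each species pair (run end-to-end by
`heterochrony_battery()`):

* **Path A** (trajectory geometry): significant angle → slope shift; else
  significant intercept → parallel trajectories; else a significant
  difference between the shapes predicted at each species' own maximum
  size → paedomorphosis/peramorphosis; else conserved.
* **Path B** (space overlap): Tfh1 asks whether the pair overlaps in
  size–shape space (ontogenetic scaling is the *null* and is deliberately
  not multiplicity-corrected, keeping the test conservative in favour of
  heterochrony); where Tfh1 rejects, Tfh2 asks whether the pair still
  overlaps in shape space alone (size–shape dissociation as the null).

One methodological point deserves care. The descriptive statistics of the
Tfh tests — pooled residual SS about the common regression (Tfh1) and
pooled perpendicular SS about the regression line in shape space (Tfh2) —
are unchanged by relabelling specimens, so a label permutation cannot move
them. The permutation comparisons therefore use label-dependent
counterparts with the same nulls: Tfh1 permutes the *excess* of the pooled
residual SS over the separate per-species fits, and Tfh2 permutes a
cross-projection SS (each specimen's squared shape-space distance to the
*other* species' line). The cross-projection form matters: an
excess-of-fits statistic for Tfh2 is anticonservative precisely in Tfh2's
null configuration, where the two species occupy one shape trajectory at
different sizes and labels are informative about size. Tfh2 projects onto
the infinite line through the pooled predictions by default (`clamp =
TRUE` restricts to the fitted segment); the construction it follows reads
"nearest point on the regression line", which we take literally.

## Juveniles versus adults

For clades whose HOST rejects a shared slope, the D test contrasts
disparity among predicted juvenile shapes ($D_j$, summed pairwise Euclidean
distances — the sum, not a mean-square, following the construction it
implements) with disparity among predicted adults ($D_a$):
$D = D_j - D_a$, negative under ontogenetic divergence. The null
re-draws two random specimens per species as stage representatives, and the
p-value is one-sided on the side of the observed sign.

Phylogenetic signal uses the multivariate generalization of Blomberg's K
(expectation 1 under Brownian motion; exactly 1 on a star tree), with
tip permutation for significance, and ΔK = K(adults) − K(juveniles) tested
against the same two-specimen resampling null. The phylogenetic MANOVA
reduces shape to the PCs holding ≥ 95% of variance (covariance-based — the
shape variables share units), fits `PCs ~ size + habitat + size:habitat`
with sequential distance-based F statistics, and simulates the null from a
multivariate Brownian model whose rate matrix is the ML estimate on those
PCs, keeping predictors fixed (simulating the response only). Species that
shift habitat between stages form their own composite category in
trajectory-level analyses. Phylomorphospace and "phyloallomspace" node
coordinates come from ML Brownian ancestral estimation; plotting is left to
the caller.

## Evolution of trajectory attributes

Eight trait-evolution models are fitted to trajectory lengths and to the
first principal component of the slope vectors (covariance PCA over
species): BM; BM with per-regime rates on a painted tree (non-censored: one
root state, per-regime time accumulating along shared paths); OU; OU with
one optimum per regime; early burst ($\sigma^2 e^{rt}$, $r \le 0$);
matching competition (lineage means attracted toward the mean of
co-occurring lineages at rate $S \le 0$); and linear/exponential diversity
dependence of the rate on the co-occurring lineage count. Competition is
restricted to sympatric taxa via a binary matrix held constant along the
tree — the exercisable stand-in for reconstructed co-occurrence histories,
which are inputs here, not something the package estimates. Comparison is
by AICc and Akaike weights.

Numerical choices worth knowing:

* OU defaults to the conditional, fixed-root covariance (root held at the
  optimum), because that variant nests BM continuously as $\alpha \to 0$ —
  a property the test suite checks; a stationary-root variant is available
  by argument.
* Base rates are profiled out analytically everywhere, so each interaction
  model needs only a one-dimensional bounded search (multi-started); the MC
  covariance is integrated through branching events as a matrix ODE, the
  diversity-dependent covariances in closed form per inter-event epoch.
* All likelihoods are invariant to tip order; rank-deficient optimum
  designs (e.g. a painting in which every tip shares one regime history)
  pin the aliased optima rather than failing.

## Branch-specific rates

Phylogenetic ridge regression assigns a signed rate to every branch so that
root-to-tip sums of rate × branch length reproduce the tip values, with an
L2 penalty chosen by leave-one-out cross-validation on tip predictions over
a log-spaced grid (the criterion is stated explicitly here because the
method family leaves it undocumented; both grid and criterion are
arguments). The trait itself can be supplied as a covariate: log absolute
rates are regressed on branch-wise covariate reconstructions and the
residuals used, so species with large ontogenetic change do not get
inflated rates mechanically.

The clade shift search compares each clade of ≥ 6 species (subtree plus
stem) against the background by the difference in mean absolute rate, with
a shuffled-rates null and flags at p > 0.975 (faster) / p < 0.025 (slower);
ties in the null count half, so a perfectly flat rate field flags nothing.
Rates enter this statistic on the absolute scale — log-transforming
absolute rates is a visualization convention, and a log-scale contrast
loses real detection power to its heavy left tail (75% versus 91% flags of
an implanted ten-fold clade in the simulation the test suite runs).
Robustness resampling re-estimates everything over trees with 25% of tips
dropped and 25% of node ages jittered within their parent–child brackets,
protecting nodes with posterior support above 0.95, and reports the
proportion of iterations recovering each shift at the MRCA of its surviving
species.

## What the synthetic generator does and does not emulate

`simulate_dataset()` produces the structure every stage assumes: a
pure-birth tree scaled to unit height; slope and intercept vectors evolving
along it under BM (or OU); six-category habitat histories from a symmetric
Markov process with an exactly enforced fraction of juvenile→adult habitat
shifts; and specimen-level series with sizes uniform over each species'
range and isotropic Gaussian shape noise. Defaults are chosen to resemble a
clade-scale museum study of lizard ontogenetic series: tens of species,
5–50 specimens per species, about 1.8 natural-log units of within-species
growth (roughly a six-fold size range from hatchling to adult),
phylogenetically structured base sizes, and residual noise of 0.05 on the
log-shape scale — small relative to ontogenetic shape change, as is typical
for morphometric data.

The generator deliberately does *not* mimic the empirical covariance of
real specimens: shape noise is isotropic, sizes are uniform rather than
museum-biased toward adults, trajectories are exactly linear, and landmark
emission (thin-plate-spline warps of a template) is optional and
exercises only the alignment machinery. Passing calibration and recovery
tests on these fixtures therefore demonstrates that the *statistical
machinery* is correct and calibrated under its own assumptions — not that
those assumptions hold in any particular empirical system.

## Validation battery and problem sizes

The test suite and the reproducibility script run the same battery, at
sizes chosen to keep Monte Carlo error well below the tolerances being
checked while remaining desk-scale: type-I calibration of HOST, the
isometry test, Tfh1 and the phylogenetic MANOVA over 1,000 simulated null
datasets with 999 permutations each (q = 6, 30 specimens per species);
closed-form oracle checks (pooled OLS via normal equations, two-specimen
GPA via SVD superimposition, one-semilandmark sliding via dense grid
search, the three-taxon BM density, hierarchical partitioning's $R^2$
identity) at tolerances 1e-9 to 1e-4; Brownian calibration of K (500 trees
of 50 tips) and of the BM rate estimate (200 trees of 100 tips); detection
power of the D test (strength-5 divergence fixtures) and of the clade
shift search (ten-fold rate clades of 12–20 tips in 40-tip trees, the
clade scale the robustness example fixes); and classification of every
constructed trajectory fixture. Fixture classifications hinge on null
hypothesis tests at α = 0.05, so a run with an unlucky seed can flip a
marginal pair; the constructed effects are sized to make this rare.

## Known limitations

* Trajectories are linear in log size; curvilinear ontogenies are summarized
  by their best linear approximation.
* Heterochrony classification identifies paedomorphosis/peramorphosis
  patterns only; without age data, the underlying process (progenesis,
  neoteny, acceleration, hypermorphosis) is unidentifiable.
* The sympatry structure is static along the tree unless time-sliced masks
  are supplied; biogeographic reconstruction is out of scope.
* Only 2D landmarks are supported, with no missing-landmark estimation.
* The MANOVA's Brownian null estimates its rate matrix from the data, so
  its calibration is asymptotic rather than exact — the test suite verifies
  it empirically at the study scale.
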