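# ontotraj

Comparative analysis of **ontogenetic allometric trajectories**: how shape
changes with size as animals grow, and how those growth trajectories
themselves evolve across a clade.

The package is aimed at evolutionary morphologists working with
specimen-level morphometric series (linear measurements or 2D landmarks)
for many species plus a time-calibrated phylogeny — the kind of data
produced by measuring museum ontogenetic series across a lizard, snake or
fish radiation.

## The model at the core

Within species $i$, shape $y \in \mathbb{R}^q$ (log-shape ratios or
Procrustes coordinates) is a linear function of log size $s$:

$$ y = a_i + \beta_i\, s + \varepsilon,\qquad \varepsilon \sim \mathcal N(0, \sigma^2 I_q) $$

The trajectory attributes — direction $\beta_i/\lVert\beta_i\rVert$, length
$L_i = \lVert \hat y_i(s_{\max,i}) - \hat y_i(s_{\min,i}) \rVert$, and
intercept $a_i$ — feed a battery of permutation and comparative tests:

* **Shape extraction** — log-shape ratios with a pooled geometric-mean size;
  GPA with bending-energy semilandmark sliding and object symmetry;
  sexual-dimorphism filtering (`log_shape_ratios`, `gpa`,
  `slide_semilandmarks`, `symmetric_component`, `dimorphism_filter`).
* **Trajectory tests** — per-species isometry test, homogeneity-of-slopes
  test (HOST), pairwise angle/length/intercept comparisons with
  residual-randomization nulls, hierarchical partitioning of adult
  disparity (`isometry_test`, `host_test`, `pairwise_trajectories`,
  `intercept_test`, `hier_part`).
* **Heterochrony** — peramorphosis test, ontogenetic scaling (Tfh1) and
  size–shape dissociation (Tfh2), and the two-path classification of every
  species pair (`peramorphosis_test`, `tfh1`, `tfh2`, `classify_pair`,
  `heterochrony_battery`).
* **Juveniles vs adults** — ontogenetic convergence/divergence test
  ($D = D_j - D_a$), multivariate Blomberg's K and the ΔK contrast,
  simulation-based phylogenetic MANOVA, phylomorphospace coordinates
  (`d_test`, `k_mult`, `delta_k_test`, `phylo_manova`,
  `phylomorphospace_coords`).
* **Trajectory evolution** — eight trait-evolution models (BM, multi-rate
  BM, OU, multi-optimum OU, early burst, matching competition, linear and
  exponential diversity dependence) compared by AICc weights; branch
  rates by phylogenetic ridge regression with clade shift search and
  robustness resampling (`fit_gauss_model`, `fit_interaction_model`,
  `compare_models`, `rr_rates`, `search_shift`, `overfit_rr`).
* **Synthetic data** — a generator for trees, habitat histories, and
  specimen-level ontogenetic series with known truth
  (`simulate_dataset`, `make_heterochrony_fixtures`,
  `make_divergence_fixture`).

See the vignette (`vignettes/ontogenetic-trajectories.Rmd`) for the
statistical details and design choices.

## A worked example

```r
library(ontotraj)

ds <- simulate_dataset(sim_spec(n_species = 20, n_specimens = c(10, 30),
                                q_traits = 6, seed = 42))
host_test(ds$shape, n_perm = 999, seed = 1)
#> Homogeneity of slopes test: F = 25.84 (df 19, 373), p = 0.001 [999 perms]

d_test(ds$shape, n_perm = 999, seed = 2)
#> D test: D = -99.25 (D_j = 182.3, D_a = 281.5), p = 0.001

fit <- fit_unique_allometries(ds$shape)
head(fit$trajectories$lengths, 3)
#>      sp01      sp02      sp03
#> 0.3855754 0.6962314 0.3659095
```

The HOST rejection (`p = 0.001`) says species do not share one allometric
slope, so each species gets its own trajectory. The negative `D` with
`p = 0.001` indicates ontogenetic divergence: predicted juveniles are more
similar across species than predicted adults, with the summed pairwise
adult distances (`D_a = 281.5`) far exceeding the juvenile ones
(`D_j = 182.3`). Trajectory lengths are in log-shape units — the magnitude
of shape change each species traverses between its smallest and largest
observed sizes.

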