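# kincycle

Inheritance of cell-cycle length on lineage trees.

Time-lapse tracking of proliferating cells yields deep lineage trees in
which cycle-length correlations show a puzzling structure: correlations
with ancestors vanish within one or two generations, while sisters, first
cousins and even second cousins stay correlated. Under single-factor
inheritance, cousins would correlate as ρ<sub>ss</sub>ρ<sub>md</sub>² and
second cousins as ρ<sub>ss</sub>ρ<sub>md</sub>⁴ — far less than observed.
`kincycle` is for researchers analysing such trees (cancer cell lines,
stem cells, microbes). It provides:

* **Tree handling and correlation patterns** — a TSV lineage-tree format
  (`read_tree_table`), kinship-resolved Spearman correlations with
  tree-level bootstrap confidence bounds (`correlation_pattern`), and a
  censoring-aware truncation rule (`truncate_trees`) that removes the bias
  caused by finite observation time.
* **Bifurcating autoregressive (BAR) models** — Gaussian latent-variable
  inheritance down a binary tree: daughter mean **A**x, unit intrinsic
  noise, sister noise coupling γI, observed score α′x. Exact whole-tree
  likelihoods (`tree_loglik`), maximum-likelihood fits (`fit_bar`, an S3
  model object with `coef`/`logLik`/`predict`/`simulate` methods),
  likelihood-ratio credible bands (`credible_band`), and Bayesian model
  evidence by Monte-Carlo integration (`log_evidence`, `bar_evidence`)
  over a catalogue of six inheritance structures (II–VII).
* **A growth–progression simulator** (`simulate_gp_trees`) — heritable
  cycle-progression speed (log-normal τ<sub>p</sub>), exponential or
  logistic cell growth, and a minimum-size division checkpoint:
  τ = max(τ<sub>g</sub>, τ<sub>p</sub>). This minimal physical model
  realises the selected BAR structure and reproduces the paradoxical
  pattern.
* **ABC fitting and perturbation predictions** — rejection ABC of the
  simulator against an observed pattern and cycle-length distribution
  (`fit_gp_abc`), posterior predictive bands, and predictions for how the
  cousin / mother–daughter correlation ratio shifts when growth or cycle
  progression is slowed (`predict_perturbation`).
* **Synthetic data** (`generate_dataset`) — full imaging-experiment
  emulation including per-cell loss, death and movie-end censoring.

## Worked example

Simulate a 40-tree, 150-hour "movie" from a coupled two-variable
inheritance model, correct for censoring, and ask which inheritance
structure the data support:

```r
library(kincycle)

p <- bar_params(matrix(c(0.55, 0, -0.5, 0.55), 2, 2), gamma = 0.35,
                alpha = c(0.5, 0.5))
movie <- generate_dataset("bar", p, n_trees = 40,
                          obs = observation_model(0.01, 0.005, 150),
                          seed = 11)
trees <- truncate_trees(movie)
trees
#> Lineage forest: 2438 cells in 40 tree(s), generations 0-5
#>   fates: censored=1, died=11, divided=2399, lost=27
#>   truncated at generation 5

correlation_pattern(trees, n_boot = 1000, seed = 2)
#> Cycle-length correlation pattern (Spearman, tree-level bootstrap CI)
#>  u v           kinship    rho  ci_low ci_high n_pairs reliable
#>  0 1   mother-daughter 0.3317  0.2850  0.3770    2359     TRUE
#>  0 2       grandmother 0.0963  0.0448  0.1365    2280     TRUE
#>  0 3 great-grandmother 0.0138 -0.0574  0.0827    2123     TRUE
#>  1 1           sisters 0.4955  0.4423  0.5408    1160     TRUE
#>  1 2        aunt-niece 0.1776  0.1270  0.2183    2254     TRUE
#>  2 2     first cousins 0.1976  0.1332  0.2612    2217     TRUE
#>  1 3        great-aunt 0.0589 -0.0125  0.1163    2101     TRUE
#>  3 3    second cousins 0.0768  0.0135  0.1327    4089     TRUE
```

The signature is visible directly: the ancestral correlations (0,2), (0,3)
collapse while first cousins at (2,2) correlate about twice as strongly as
the single-factor null ρ<sub>ss</sub>ρ<sub>md</sub>² ≈ 0.05 would allow.
Model comparison agrees — the coupled two-variable model V dominates the
single-variable model II and the uncoupled two-variable model III:

```r
bar_evidence(trees, models = c("II", "III", "V"), n_mc = 2000, seed = 3)
#> BAR model comparison (Monte-Carlo evidence)
#>  model log_evidence mc_se  ess relative_evidence
#>     II        -3129 0.458 4.76          0.000143
#>    III        -3127 0.669 2.24          0.001019
#>      V        -3121 0.871 1.32          1.000000

fit_bar(trees, "V", seed = 4)
#> BAR model V fit: 2399 cells in 40 trees, log-likelihood -3106.08
#> coefficients:
#>      a    a12  gamma alpha1
#>  0.568 -0.578  0.387  0.404
```

The fit recovers the generating parameters (a = 0.55, a₁₂ = −0.5,
γ = 0.35, α₁ = 0.5) from a single simulated experiment.

The mechanistic counterpart runs the same analysis from physical
assumptions instead of latent variables:

```r
gp <- simulate_gp_trees(gp_params(), n_trees = 30, n_gen = 7, seed = 1)
limitation_fractions(gp)       # share of growth- vs progression-limited cycles
ancestral_stats(gp)            # autocorrelations and the negative tau_p-tau_g coupling
fit_gp_abc(truncate_trees(gp), n_sims = 5000, seed = 2)  # rejection-ABC fit
```

See the vignette (`vignettes/cell-cycle-inheritance.Rmd`) for the models,
their assumptions, parameter meanings and numerical choices.

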