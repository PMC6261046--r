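# cortisim

Agent-based simulation of how cortico-cortical connectivity can come to
mirror architectonic differentiation during development.

Across mammalian species, cortical areas of similar architectonic
differentiation (proxied by neuron density) are connected more frequently
than dissimilar areas, beyond what their spatial proximity explains — the
*architectonic type principle*. `cortisim` implements an in-silico test of
a developmental explanation: a two-dimensional cortical sheet of
equal-size square areas grows around one to four neurogenetic origins
while point neurons extend axons as random walks and form synapses
stochastically on proximity (Peters' rule). Because the wiring rules are
identical across all 21 spatiotemporal growth layouts — planar growth with
a realistically oriented density gradient (later areas denser), an inverse
gradient, a random gradient, radial in-place growth, or a static sheet —
any difference in the resulting area-level connectomes is attributable to
*when and where* neurons were generated.

The package provides, for each simulated instance:

- the directed binary area-level connectome with per-pair axon counts,
  plus pairwise structural measures (signed/absolute neuron-density
  difference, Euclidean centroid distance);
- binned relative connection frequency with exact small-sample Spearman
  rank correlations (minimum attainable two-sided p across four tiers:
  2/4! = 0.083);
- binary logistic edge prediction with McFadden's pseudo-R² =
  1 − LL_model/LL_null for distance, |Δdensity| and both;
- area degree versus density correlations;
- cross-instance aggregation by medians and left-tailed sign tests
  (z = (2S − n + 1)/√n; 100 instances all significant gives z = −9.9);
- a linear-kernel SVM trained on simulated pairs (uniform class priors,
  sigmoid-calibrated posteriors) applied with dual posterior thresholds
  (0.750–0.975) to connectivity tables in the empirical tract-tracing
  format, validated against 100-permutation chance distributions, with
  accuracy, Youden's J, fraction classified, and a three-way ANOVA
  (species × growth mode × origins) with Bonferroni post-hoc tests;
- a generator for synthetic empirical-format fixtures with a planted,
  tunable architectonic-type signature, so the whole pipeline runs
  without any external data.

## Worked example

```r
library(cortisim)

layout <- get_layout("1D-1row-2or")   # realistic gradient, 1 row, 2 origins
result <- run_instance(layout, seed = 42)
result
#> <sim_result> 1D-1row-2or seed=42: 8200 neurons, 8200 synapses, occupancy 1.0000

conn <- aggregate_connectome(result$synapses, result$neuron_area,
                             n_areas = nrow(result$sheet$areas))
conn
#> <area_connectome> 26 areas, 418 connections (min_axons=1), density 0.643

report <- analyze_instance(conn, structural_measures(result$sheet),
                           sheet_areas(result$sheet))
round(t(report), 3)
#> fraction_connected   0.643
#> n_connections      418.000
#> rho_distance        -0.952
#> p_distance           0.000
#> rho_density         -0.857
#> p_density            0.024
#> n_bins_density       7.000
#> r2_distance          0.193
#> r2_density           0.036
#> r2_both              0.249
#> rho_degree          -0.536
#> p_degree             0.005
```

Reading the report: 64% of the 650 possible directed area pairs are
connected; the relative frequency of present connections falls steeply
with distance (ρ = −0.95) and with absolute density difference across the
7 density tiers (ρ = −0.86, exact p = 0.024); both measures jointly
improve logistic edge prediction over the constant-only null (McFadden
R² = 0.25); and denser (later-born) areas maintain fewer connections
(ρ = −0.54) — the architectonic-type signature. Running the same analysis
on a `static-`, `radial-` or `random-` layout removes the density effects
while the distance effect persists.

Cross-instance and classification workflows:

```r
camp <- run_campaign(list(layout), n_instances = 11, base_seed = 1)
camp$aggregate             # medians + sign tests, one row per layout

pairs <- pair_table(conn, structural_measures(result$sheet))
clf <- train_classifier(pairs[, c("abs_density_diff", "distance")],
                        pairs$exists)
fx <- generate_fixture(fixture_spec(n_rows = 1128), seed = 99)
evaluate_classifier(clf, fx)  # accuracy / Youden J / fraction classified
                              # per threshold, permutation-validated
```

A thin command-line wrapper ships as `inst/exec/cortisim` with verbs
`grow`, `simulate`, `analyze`, `fixtures` and `calibrate`.

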