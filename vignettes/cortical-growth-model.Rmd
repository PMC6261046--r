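---
title: "Modelling cortical sheet growth and the emergence of density-linked connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cortical sheet growth and the emergence of density-linked connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortisim)
```

## The scientific question

Across mammalian cortices, areas of similar architectonic differentiation
are connected more frequently than dissimilar ones, beyond what spatial
proximity explains — the architectonic type principle (ATP). One proposed
mechanism is developmental: if the cortical sheet grows planarly around a
small number of neurogenetic origins, if later-born areas are more
differentiated (denser in neurons), and if axons grow randomly and synapse
stochastically on proximity, then neurons born in nearby time windows are
both near each other while their axons grow and similar in density — so a
density–connectivity association emerges without any targeted wiring.

`cortisim` implements this in-silico experiment: a growing two-dimensional
cortical sheet of equal-size square areas, populated by point neurons that
extend one axon each as a random walk and form synapses by Peters'-rule
proximity, followed by the full analysis battery that relates the
resulting directed area-level connectomes to neuron density and distance,
and a simulation-trained classification framework for connectivity tables
in the tract-tracing format.

## Growth layouts

Twenty-one spatiotemporal growth layouts are enumerated by
`make_layout_registry()`, organised as five sets x three growth modes:

* **realistic** — planar growth around origins; each growth event adds new
  areas at the fringes with a *higher* density tier than all earlier areas.
  Implemented with 1, 2 and 3 origins (1D modes) or 1, 2 and 4 origins
  (2D mode).
* **inverse** — planar growth, density tiers *decreasing* with time.
* **radial** — the sheet has its final geometry from the start; every
  growth event adds the same number of somata to every unfinished area, so
  dense areas keep growing longer.
* **static** — the complete sheet with all neurons exists from time 0.
* **random** — planar growth, but each new area draws its density from a
  seeded permutation of the realistic set's density multiset, removing the
  time–density link while preserving the density distribution.

Growth modes are a single row of areas extending along one axis
(`1D_1row`), two stacked rows (`1D_2rows`), or concentric square rings
(`2D`). Growth-event counting follows the published layout sizes: in 1D
modes the origin areas pre-exist and each event adds one area per side per
origin per row (1 origin, 12 events: 1 + 12x2 = 25 areas); in the 2D mode
the first event places the origin areas and each later event adds one full
ring per origin (5 events: (2x4+1)^2 = 81 areas per origin). Multi-origin
2D blocks sit on a line (two origins) or a 2x2 grid (four); the exact
arrangement of multiple origin blocks is not uniquely determined by the
published material, and the contiguous block arrangement used here is a
design choice. Because blocks stay contiguous and grow at their fringes,
every growth event weakly increases all pairwise distances between
existing areas, which the test suite asserts as an invariant.

Neuron density rises linearly from `density_min` to
`density_fold * density_min` (default fold 5, mirroring the roughly
five-fold empirical range) across a layout's tiers; a layout has one tier
per growth event (2D) or one per event plus the origin tier (1D). Absolute
densities are not published for the original experiment, so per-area soma
counts are a free scale; the default `density_min = 100` puts 100–500
somata in each unit-square area, large enough for stable area-level
statistics and small enough that a hundred instances of any layout remain
cheap. Somata sit on a regular, cell-centred grid (the factor pair of the
soma count closest to square, ties toward more rows).

## Axon dynamics

Each neuron owns exactly one axon terminal, created at its soma the moment
the soma appears. Per time step every unoccupied terminal extends by
`step_length` at a uniformly random angle, reflecting off the current
sheet boundary. A terminal becomes *eligible* once it has left its parent
area, and from then on it may synapse onto any soma (its own excluded)
that comes closer than `contact_radius`: the nearest in-range soma is the
candidate (exact ties broken uniformly at random), and the contact is
realised with probability `accept_prob = 0.9`; otherwise the axon simply
keeps growing and may retry later. A successful contact freezes the
terminal at the soma position permanently. When a growth event re-lays-out
the sheet, every terminal is translated with the area containing it
(point-in-rectangle lookup on the pre-event layout; points outside all
areas snap to the nearest area), so established synapses are stretched but
never broken. All growth events are scheduled evenly within the first
third of the simulated duration, with the last event exactly at
`floor(T/3)`.

The per-step update is implemented twice: a compiled kernel (used by
`run_instance()`) and a pure-R reference (`sim_step()` =
`extend_unoccupied_terminals()` + `attempt_synapses()`). Both consume
random draws in the identical documented order — per step, one angle per
unoccupied terminal in neuron-id order, then per candidate-holding
terminal an optional tie-break draw followed by an acceptance draw — so
the two paths are bit-identical for the same seed, which the test suite
checks. The kernel buckets somata on a uniform grid with cell size at
least `contact_radius`, a performance measure that leaves results
unchanged.

## Calibration

The free parameters (`step_length`, `contact_radius`, total duration) are
fixed by the calibration criteria of the original study: at the end of a
run at least 99.9% of terminals must be occupied, and the fraction of
ordered area pairs connected by at least one axon in 1D layouts must fall
in the empirically reported 39–66% band. `calibrate()` runs this search on
pilot instances. The shipped defaults (`default_sim_params()`) are its
products: `step_length = 1.0`, `contact_radius = 0.013`, `T = 300` for the
1D modes and `step_length = 1.0`, `contact_radius = 0.006`, `T = 450` for
the 2D mode (units: sheet lengths with `area_side = 1`; one area is one
unit square). Two observations from the calibration are worth recording.
First, occupancy and connectivity constrain only the product of contact
hazard and walk length, leaving a one-parameter family of admissible
settings. Within that family, settings in which synapses form throughout
the growth era — rather than mostly after the sheet is complete — are the
ones that reproduce the developmental mechanism under study (connections
formed early between then-adjacent areas are stretched by later growth),
and the defaults were chosen in that regime. Second, the 2D mode needs a
smaller contact radius (denser local soma neighbourhoods) and a longer
tail after growth for the occupancy criterion, which is why its duration
is 450 steps; all growth still completes by step 100.

## Per-instance analyses

`analyze_instance()` reproduces the per-instance record used throughout
the study:

* **Binned relative connection frequency** — ordered area pairs are binned
  by a structural measure; each bin reports
  `n_present / (n_present + n_absent)`. Distance always uses 10
  equal-width bins over the observed range; absolute density difference
  uses one bin per tier when the layout has at most 10 tiers. Tier
  detection rounds to 8 significant digits so floating-point noise in tier
  differences cannot split a tier. Empty bins carry an undefined frequency
  and are dropped before correlating.
* **Spearman rank correlation** — average ranks for ties; for up to 7
  retained bins the two-sided p-value is computed by exhaustive
  enumeration of rank permutations (the discrete minimum at 4 bins is
  2/4! = 0.083, at 5 bins 2/5! = 0.0167), above that by the t
  approximation. The enumeration cutoff at 7 keeps the cost of the exact
  path trivial while covering every tiered binning that arises in the
  shipped layouts; distance binning always has 10 bins and uses the
  approximation.
* **Logistic edge prediction** — four maximum-likelihood fits of existence
  on z-scored predictors (constant-only, distance, absolute density
  difference, both) and McFadden's pseudo-R2, `1 - LL_model / LL_null`,
  per non-null model. The ratio form without the `1 -` is available
  behind `printed_formula = TRUE` for auditing; the standard definition is
  the default because the conventional interpretation bands (0.10
  moderate, 0.15 adequate, 0.20 very high) apply to it.
* **Area degree** — afferent plus efferent binary connections per area,
  correlated against area density.

`aggregate_instances()` collapses instances to medians plus a left-tailed
sign test of the per-instance correlation p-values against 0.05, using the
normal approximation with continuity correction,
`z = (2S - n + 1) / sqrt(n)` with `S` the count above threshold — with 100
instances all below threshold this gives z = -9.9, p = 2.1e-23.

## Classification of empirical-format data

`train_classifier()` fits a linear-kernel support vector machine on the
z-scored simulated pair measures with class weights inversely proportional
to class frequencies (uniform priors), and calibrates posterior
probabilities by the standard sigmoid (Platt) fit on the training data —
the original study names only an SVM with posterior probabilities, so
sigmoid calibration is an assumption, stated here once. Empirical-format
measures are z-scored with the dataset's own mean and standard deviation.
The dual-threshold rule (`classify_with_threshold()`) labels a pair
present above the threshold, absent below one minus it, and leaves the
intermediate band unclassified; ten thresholds from 0.750 to 0.975 in
steps of 0.025 are evaluated and averaged per instance. Accuracy is
computed over classified rows, Youden's J = sensitivity + specificity - 1
additionally requires both truth classes among them; thresholds with
undefined metrics are dropped from the instance mean and instances with no
defined threshold are excluded from layout medians and counted. Chance
performance per threshold comes from 100 label permutations fitted to a
normal, against which the observed metric is z-tested two-sided; the
cross-instance sign test then summarises the per-instance median p-values.
`anova_origins()` runs the balanced three-way main-effects analysis of
variance (species x growth mode x origins; on the full 1800-observation
design the error term has 1794 degrees of freedom) with estimated marginal
means for the origin levels and Bonferroni-corrected pairwise z-tests
using the model residual variance.

## Synthetic empirical-format fixtures

Real tract-tracing tables are not shipped. `generate_fixture()` produces
synthetic stand-ins with the same column structure (directed pair, binary
existence, differentiation measure, distance measure) and a planted ATP
signature: areas receive uniform differentiation levels (optionally
discretized into up to 8 ordinal levels, cortical-type style) and planar
positions; existence is drawn from a logistic model whose coefficients
penalise absolute differentiation difference and distance, with the
intercept solved numerically so the expected connectivity equals the
configured base rate (default 0.6, inside the empirically reported
0.50–0.77 range). The default effect sizes (1.5 log-odds per standardized
unit of differentiation difference, 1.0 per unit distance) produce binned
existence frequencies that decline clearly over both measures, comparable
in strength to the reported empirical regularities. What the fixtures do
*not* emulate: spatial autocorrelation of real parcellations, asymmetric
reciprocity, species-specific distance distributions, measurement noise in
tract tracing. Passing the transfer tests therefore shows that the
pipeline detects an ATP-consistent structure when present — not that any
particular empirical dataset would be predicted at the published
accuracies, which depend on the real data and are out of scope here.

## Problem sizes and reproducibility

The shipped test-suite and acceptance analyses use 11 seeded instances per
layout where distributions over instances are needed, and 5 where only a
sign-test contrast is required; these sizes were chosen as the smallest
that make the cross-instance sign tests decisive (with 11 instances all
below threshold the sign test reaches p = 0.0035) while keeping a full run
of the battery a matter of minutes on a laptop. A full-scale replication
with 100 instances per layout is a single `run_campaign()` call. Every
stochastic component — sheet construction, axon dynamics, permutation
nulls, fixtures — draws from R's RNG under one seed per instance, and
campaign instance `i` always receives `base_seed + i - 1`, so all tables
are reproducible bit-for-bit.

## Known limitations

The model inherits the idealisations of the original design: a flat,
rectangular, single-hemisphere sheet; one axon per neuron; no pruning,
waiting periods, laminar structure or activity-dependent remodelling;
Euclidean distance on the sheet as the proximity measure. Within-area
synapses are simulated but ignored by the area-level analyses. The
absolute neuron-density scale is arbitrary (only the five-fold gradient is
anchored), so quantities that depend on absolute axon counts — e.g. the
effect of the 10-axon existence threshold — should be interpreted relative
to the density scale in use. Finally, posterior calibration of the SVM and
the arrangement of multiple 2D origin blocks are assumptions, as noted
above.
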