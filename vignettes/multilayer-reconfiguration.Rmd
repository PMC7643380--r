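---
title: "Longitudinal multilayer network reconfiguration: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal multilayer network reconfiguration: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longnet)
```

## The problem

Resting-state functional connectivity changes slowly over years, and a
natural question in aging research is *how* the brain's modular
organization reconfigures over such intervals: do regions keep their
network allegiances, do whole subnetworks drift together, or do individual
regions wander off on their own? `longnet` implements a complete analysis
chain for this question: per-occasion connectivity layers are stacked into
an ordinal multilayer network per subject, community structure is
estimated jointly across occasions by multilayer modularity maximization,
temporal reconfiguration is summarized by five metrics, observed values
are referenced against temporal and nodal null models, and subject-level
metrics are related to age and cognitive change.

Because longitudinal neuroimaging cohorts are rarely shareable, the
package also contains a first-class synthetic cohort generator whose
ground truth makes every downstream stage testable: the generator plants
the switching events that the metrics are designed to count, so the two
modules audit each other exactly.

## Connectivity layers

Each occasion's `T x N` ROI time-series matrix is reduced to an `N x N`
Pearson correlation matrix, Fisher r-to-z transformed, and restricted to
positive weights (negative values and the diagonal are set to zero).
Negative correlations are ambiguous under global signal regression, so the
analysis operates on positive weighted networks throughout. Two numerical
choices matter here:

* correlations of exactly ±1 are clipped to ±(1 − 10⁻⁷) before `atanh`, so
  degenerate pairs yield large finite weights rather than infinities the
  optimizer cannot process;
* the optional significance-thresholded variant (`fdr_threshold()`)
  converts each unique pair's r to a two-sided p through
  `t = r·sqrt((T−2)/(1−r²))`, applies Benjamini–Hochberg across the
  `N(N−1)/2` unique pairs at `alpha` (0.01 in the thresholded analysis),
  and zeroes non-survivors. Correction is per subject; p-values are not
  pooled across subjects. BH is used because "FDR-adjusted" without
  qualification conventionally means BH in this field.

Layers are joined *by node label*, not file order, and subjects lacking
any occasion are rejected: the temporal analysis is only defined on
complete longitudinal data.

## Multilayer modularity

For layers `l = 1..L` with weights `A_ijl`, node strengths
`k_il`, layer totals `2m_l = Σ_ij A_ijl`, and community assignments
`g_il`, the quality function is

$$Q = \frac{1}{2\mu} \sum_{ijlr} \left[ \left(A_{ijl} - \gamma\,
\frac{k_{il}k_{jl}}{2m_l}\right)\delta_{lr} + \delta_{ij}\,\omega_{jlr}
\right] \delta(g_{il}, g_{jr})$$

with ordinal interlayer coupling `ω_jlr = ω` for `|l − r| = 1` and zero
otherwise, and `2μ` the total of intralayer strengths plus interlayer
coupling strengths. Two conventions for `m_l` circulate in the
literature — total layer weight versus average edge weight; `longnet`
uses the standard Newman–Girvan total-weight convention, which is what
the canonical generalized-Louvain implementations compute. `γ` is held
constant across layers.

* **γ (structural resolution, default 1):** scales the null model; larger
  values produce more, smaller communities. The package verifies (and the
  test suite asserts) that ensemble-mean module count is non-decreasing in
  γ on planted networks.
* **ω (temporal coupling, default 1, dimensionless weight):** rewards
  temporally consistent assignments. Larger ω makes layers more similar,
  so mean flexibility is non-increasing in ω; in the limit the partition
  is constant across layers.

`genlouvain_optimize()` maximizes Q on the `NL`-supra-node graph with the
two-phase Louvain scheme; the inner loop is compiled (Rcpp) and driven by
R's RNG so every run is seed-reproducible. The default move rule is
`moverandw`: among strictly improving moves one is chosen with probability
proportional to its gain, which avoids a known pathology of the greedy
rule under ordinal coupling. The greedy `move` rule (best improving move,
RNG tie-breaks) is also available. Because the algorithm is stochastic,
`repeated_optimization()` runs it 100 times by default and all metrics are
ensemble-averaged; the test suite and analysis scripts use 10–50 restarts,
which we found indistinguishable in cohort-level summaries at the
simulated effect sizes.

Every returned Q is, by construction, re-derivable from the partition;
`evaluate_Q()` is an independent layer-by-layer implementation of the
formula above and the suite requires agreement to 10⁻¹⁰ on every run. An
all-zero layer makes `2m_l` undefined and is rejected. Community ids are
canonicalized by first appearance (nodes within layer 1, then layer 2, …)
so equal partitions compare bit-stably.

## Temporal metrics

With `P` an `N x L` partition:

* **Flexibility** — switches across consecutive layers / (L − 1).
* **Promiscuity** — distinct communities visited / K. K is the number of
  distinct communities in *that* partition; an ensemble-wide denominator
  can be supplied via `total_communities`. The phrase "all communities" is
  ambiguous between these two readings; the per-partition reading is the
  default because it keeps the metric self-contained per optimization.
* **Cohesion matrix / strength** — pair (i, j) is credited once per
  transition at which both move from the same source community to the same
  destination; strength is the row sum, a raw unbounded count (this is the
  scale on which cohort cohesion intercepts near 19 arise in real-data
  analyses of this kind).
* **Disjointedness** — switches made by a node *alone* (no other node
  makes the same source→destination move at that transition) / (L − 1).
  A community splitting into subgroups, or merging into another, therefore
  yields cohesion without disjointedness.
* **Allegiance** — fraction of (layer, optimization) instances in which
  two nodes share a community, pooled over the whole ensemble; diagonal 1.
* **Recruitment** — a node's mean allegiance to the other members of its
  predefined resting-state network, self-allegiance excluded (including
  the diagonal would inflate every node's score by a constant). A node
  whose network has no second member is flagged NA and excluded from
  network and global averages.

Flexibility, promiscuity, cohesion and disjointedness are computed per
optimization and averaged; recruitment is computed from the pooled
allegiance matrix — both orderings are equivalent for allegiance-based
quantities. Network-level values are means over member nodes (rather than
re-estimating metrics on subgraphs), matching standard practice.

## Null models

* **Temporal null** — layers reordered by a uniformly random permutation
  (identity permitted; with L = 4 only 24 orderings exist). Within-layer
  connectivity is untouched, temporal dependence is destroyed.
* **Nodal null** — within each layer, off-diagonal upper-triangle weights
  are permuted over node pairs and re-symmetrized. This preserves each
  layer's weight multiset, density and symmetry exactly, and destroys
  community structure. A strength-sequence-preserving rewiring
  (Maslov–Sneppen style) would be a stricter null; the pair-permutation
  null was chosen because the target contrast — planted structure versus
  none — does not depend on preserving strength sequences, and the
  permutation null's conservation properties are exactly testable. This
  is a documented choice, not the only possible reading of "random
  rewiring within a time point".

Fifty nulls per subject (and 100 optimizations each) are the full-scale
defaults; per-subject null values are averaged across nulls *before* the
group comparison, so real and null samples have equal length — the
pooling is symmetric and keeps Welch's test honest about its units of
analysis. Comparisons use Welch's two-sample t with Satterthwaite degrees
of freedom, pooled-SD Cohen's d (bands: ≥0.2 small, ≥0.5 medium, ≥0.8
large), and a Bonferroni-style `α/n` threshold over the n metrics
compared.

## Group-level statistics

* **Age models** — OLS of each metric on grand-mean-centered age with
  gender (1 = female), education (ordinal 1–3, entered numerically, as is
  conventional when a single coefficient per covariate is reported) and
  mean framewise displacement as nuisance covariates. Partial η² per
  predictor comes from type-III (drop-one) sums of squares,
  `SS_eff/(SS_eff + SS_res)`, which for these 1-df terms equals the
  squared partial correlation (asserted numerically in the suite).
  Significance is assessed at `α/n_models`.
* **Metric intercorrelations** — Pearson r with Fisher-z CIs among mean Q,
  global recruitment and global flexibility; partial correlations given
  age by residual-on-residual correlation with one df subtracted.
* **Cognitive change** — the full random-slope mixed-model treatment of
  longitudinal T-scores is out of scope; `change_slopes()` instead fits
  per-subject OLS slopes of score on time (years 0, 1, 2, 4), after
  removing a cohort-level retest bump (indicator 0, 1, 1, 1) estimated
  jointly with a linear time term — estimating the bump without the time
  term would absorb part of the genuine trend. An optional
  empirical-shrinkage mode pulls noisy slopes toward the cohort mean with
  weights from the usual between/within variance decomposition; both raw
  and shrunken slopes are exposed because composite (BLUP-like) slopes
  and raw OLS slopes are both defensible inputs to change–change
  correlations. Subjects with fewer than three occasions are flagged
  missing. The closed-form check: scores (50, 49, 48, 46) at times
  (0, 1, 2, 4) give a slope of exactly −1.
* **Change–change association** — Pearson (and age-partialled)
  correlations between per-subject cognitive slopes and each flexibility
  measure (global + 7 networks), `α/n` over the family.

## The synthetic cohort generator

`sim_config()` defaults are the conditions the pipeline is meant for:

| parameter | default | rationale |
|---|---|---|
| n_subjects | 150 | complete-data longitudinal cohort size |
| ages | Beta(2, 4.55) scaled to [64, 83] | right-skewed elderly cohort; mean exactly 69.8 |
| n_nodes / networks | 200 in 7 blocks (FPCN 30, DMN 44, DAN 26, SVAN 24, LIMB 12, SM 34, VIS 30) | Schaefer-200/Yeo-7 proportions |
| n_layers / times | 4 at 0, 1, 2, 4 years | four measurement occasions |
| mu_within / mu_between | 0.5 / 0.1 (Fisher-z) | typical within- vs between-network positive FC |
| noise_sd | 0.1 | keeps planted blocks recoverable but not trivial |
| base_switch_prob | 0.4 | matches global flexibility ≈ 0.42 in elderly cohorts |
| age_effect | 0.0036 / yr | the order of reported age–flexibility slopes |
| cohesive_fraction | 0.9 | cohesion dominates disjointedness by two orders of magnitude in this literature |
| cognitive_slope_mean | −0.5 T/yr | observed decline rates in speed/memory composites |
| slope_age_effect | −0.05 | steeper decline at older ages |
| slope_sd | 0.5 | between-person slope spread (≈2 T over 4 years); sized so a 150-subject cohort recovers the mean slope to ±0.1 |
| retest_bump | 1.8 T | first-follow-up familiarity gain |

Generation is: baseline partition = the 7 planted networks; each
subsequent occasion evolves by per-node switching at
`clip(base + age_effect·(age − mean age), 0, 1)`, with a
`cohesive_fraction` of events executed as subgroup moves (a flagged
straggler on a cohesive event reuses the previous subgroup's destination
or recruits a partner, so `cohesive_fraction = 1` produces exactly zero
disjointedness); weights are block means plus Gaussian noise clipped at
zero. Weights are generated directly on the Fisher-z scale; an optional
latent-factor mode (`simulate_timeseries()`) emits ROI time series whose
correlations reproduce `tanh(mu_within)` / `tanh(mu_between)`, so the
correlation→z→positivize entry path can be exercised end to end.

Ground-truth partitions are stored, which gives two exact oracles: metrics
computed on truth must match direct event tallies, and optimizer-derived
metrics must track truth closely when structure is strong
(`mu_within ≫ mu_between`, low noise).

What the generator does **not** emulate: BOLD/hemodynamic signal
properties, head-motion artifacts and their correlation with age, scanner
or session effects, attrition, spatial autocorrelation of parcels, or
negative-edge structure. Passing tests therefore demonstrate correctness
of the estimators and the internal consistency of the pipeline under the
assumed data-generating process — not robustness to the messiness of real
fMRI.

Parameter-recovery simulations (used in the test suite) plant a
deliberately strong age effect (0.01/yr) so that the recovery check is a
test of the estimator, not of statistical power at a marginal effect
size; the default 0.0036 produces, as in real cohorts of this size,
effects near the detection boundary.

## Reproducibility and problem sizes

All randomness funnels through explicit integer seeds;
`derive_seeds()` fans a master seed into per-subject, per-null and
per-restart substreams, so any unit of work is reproducible in isolation
and whole-cohort runs are byte-identical given the same seed. The test
suite and the acceptance script run at reduced scale — 28–56 nodes, 10
optimizer restarts, 10 nulls, cohorts of 8–150 subjects — sizes at which
every qualitative property of the full-scale analysis (planted-structure
recovery, null-model contrasts, resolution/coupling monotonicity,
parameter recovery) is already stable.

## Known limitations

* The nodal null is a weight permutation, not a strength-preserving
  rewiring; effect sizes against it will exceed those against stricter
  nulls.
* Promiscuity depends on the per-partition community count K, which
  varies across optimizations; its ensemble mean therefore mixes slightly
  different denominators.
* Per-subject OLS slopes understate the shrinkage an LME would apply;
  the optional shrinkage mode approximates, but does not equal, BLUPs.
* With only four layers, flexibility and disjointedness take few distinct
  values per node (multiples of 1/3); node-level analyses lean on
  ensemble averaging for resolution.
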