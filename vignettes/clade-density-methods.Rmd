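---
title: "Clade density: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clade density: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladedensity)
```

## The question and the statistic

Models of diversity-dependent diversification posit that speciation rates
fall as a region fills with competing species. Testing that idea requires a
per-species measure of how much competitive pressure a species plausibly
experiences from its own higher taxon — not a mean-field count of species in
a region, but a measure that (i) only lets species influence one another
when they actually co-occur, and (ii) weighs close relatives (presumed
ecologically most similar) more than distant ones.

**Clade density** is that measure. With `O` the species-by-species matrix of
range-overlap areas (diagonal: range sizes) and `C` the phylogenetic
variance–covariance matrix (`C[i, j]` = depth of the most recent common
ancestor of tips *i* and *j*, i.e. their shared evolutionary time), the
clade density of species *i* is

$$CD_i \;=\; \sum_{j \ne i} O_{ij}\, C_{ij},$$

in units of area × time (km²·Myr for projected geographic ranges on trees in
Myr). An allopatric species has `CD = 0` whatever its phylogenetic position;
a species overlapping many close relatives scores high. Two switches are
deliberately exposed because the definition admits variants:

* `include_self` (default `FALSE`): whether the diagonal term
  `O_ii * C_ii` (own range × own root-to-tip depth) is added. A species is
  not its own competitor, so the default excludes it.
* the weight matrix: the default weight is the covariance `C_ij`, which is
  *large* for close relatives. The phrase "weighted by phylogenetic
  distance" could also be read as inverse-distance weighting;
  `inv_patristic_weights()` provides `1/d_ij` weights for sensitivity
  analysis. Conclusions that survive both weightings do not hinge on the
  choice.

The association between clade density and per-tip speciation rate is then
tested with ES-sim (below), repeated over an ensemble of alternative
topologies because both `C` and the rates depend on the tree.

## Range geometry

Ranges arrive as GeoJSON FeatureCollections, one feature per species
sub-range, with `presence` and `origin` attribute codes. Features coding
uncertain occurrence or introduced populations are excluded before any
measurement (`filter_spec()`; the code lists are configuration, since
attribute vocabularies differ between sources). Per-species features are
dissolved (unioned) so seasonal or subspecific sub-ranges never
double-count overlap.

All measurement runs on an exact *signed convex decomposition*: every
species range is reduced to convex pieces (triangles from ear-clipping,
plus clipped convex pieces) each carrying a sign, such that the signed sum
of piece indicators equals the indicator function of the range. Outer rings
contribute `+1`, holes `-1`, and the inclusion–exclusion terms of a union
`±1`. Because indicator functions multiply, the intersection of two ranges
is just the set of pairwise convex clips (Sutherland–Hodgman) with
multiplied signs — so areas, intersections and unions are all exact up to
floating-point rounding, with no rasterisation or tolerance snapping.
Pairs of species whose bounding boxes are disjoint are skipped; their
overlap is identically zero, so the shortcut cannot change the result (a
test compares against the exhaustive loop).

Numerical guards: convex clip outputs with fewer than 3 vertices or with
area below `1e-14 ×` (local bounding-box scale)² are dropped as degenerate;
self-intersecting ("bow-tie") rings are repaired by splitting at proper
edge crossings into simple loops, preserving covered area (coincident-edge
degeneracies are left as-is rather than guessed at).

Geographic coordinates are projected with the Lambert cylindrical
equal-area map (standard parallel 0°): `x = R·λ`, `y = R·sin φ` on a sphere
of authalic radius `R = 6371.0072` km, so planar polygon areas equal
spherical areas and high-latitude ranges are not inflated. Boundary
segments are interpreted as straight lines in projected space; for
coarse-vertex polygons spanning many degrees of latitude this is a
boundary-discretisation approximation (closed-form tests on zonal bands
and dense-boundary spherical caps hold to 0.1%).

## Tip speciation rates

The per-tip rate estimate is the inverse equal-splits measure. For tip *i*
with root-to-tip edges indexed `j = 1` (pendant) to `N_i` (root-adjacent),

$$ES_i = \sum_j l_j\, 2^{-(j-1)}, \qquad \lambda^{DR}_i = 1/ES_i .$$

The halving weights mean recent branches dominate, which is why the
statistic tracks speciation rather than net diversification. Two contracts
matter in practice:

* rates are computed on the **full** tree and then merely subset to the
  species with geographic data (`restrict_rates()`); recomputing on a
  pruned tree would delete splits and bias rates downward.
* polytomies leave the edge index ill-defined and are rejected unless a
  seeded random resolution with zero-length internal edges is requested
  (zero-length edges change no path sum).

## The ES-sim association test

`essim()` correlates a transformed trait with transformed rates and builds
the null by simulation rather than by a parametric trait–diversification
model. Steps, for trait `x` on tips shared with the tree:

1. observed statistic: Pearson correlation `rho` of `f(x)` with
   `log lambda_DR`. Defaults: `f = log(x + c)` with `c` the smallest
   positive observed value (clade density is strongly right-skewed and
   contains exact zeros), and log-rates (the convention for inverse
   equal-splits). Both transforms are pinned, reported in the result, and
   switchable to identity.
2. Brownian-motion fit of the transformed trait by generalized least
   squares: `a = (1'C⁻¹1)⁻¹1'C⁻¹x` and ML rate
   `σ² = (x−a)'C⁻¹(x−a)/n`.
3. null distribution: `n_sim` traits drawn as `a + σ·Lᵀz`, `L = chol(C)`,
   `z ~ N(0, I)` — the exact finite-sample null given the fit — each
   correlated with the same rates.
4. two-tailed `p = (1 + #{|rho_k| ≥ |rho_obs|}) / (n_sim + 1)`: with the
   conventional `n_sim = 100` the attainable values are `k/101` and `p`
   is never exactly zero.

The reported slope is the OLS slope of untransformed `lambda_DR` on the
untransformed trait, so it keeps interpretable units (rate per unit clade
density); transforms affect only `rho` and `p`.

`run_ensemble()` repeats the whole chain per topology — covariance, rates,
clade density (which changes with the tree through `C`), test — and
summarises the slope distribution and the fraction of topologies
significant at `alpha`. Every topology uses the same seed so a duplicated
topology gives an identical record, and no multiple-testing correction is
applied across topologies: the ensemble propagates phylogenetic
uncertainty; it is not a family of independent hypotheses.

## The synthetic generator and what it does (not) emulate

The generator exists so that every stage has testable ground truth.
`simulate_tree()` runs a Gillespie birth–death simulation started from two
root lineages and conditioned on first reaching `n_tips` extant lineages
(whole-clade extinction triggers a bounded retry); the stop time is drawn
inside the following inter-event interval so pendant edges stay strictly
positive, extinct lineages are pruned, and tip labels are a seeded random
permutation so species identity carries no trace of lineage birth order
(otherwise independently simulated topologies on one label set would share
hidden structure). A trait diffuses by Brownian motion along every lineage;
under the trait-dependent model each lineage speciates at
`lambda0·exp(beta·x)` with rates held constant between events and refreshed
from current traits at each event. That piecewise-constant scheme is an
approximation for `beta ≠ 0` but *exact* for `beta = 0`, which is the case
the moment-calibration tests rely on (standardised tip traits
`L⁻ᵀx/σ` pooled over replicates are standard normal).

`simulate_ranges()` places a square (or 64-gon disc) per tip, centred on a
2-D Brownian motion along the tree, so close relatives sit near each other
and overlap more — the premise the statistic is built on. Areas are drawn
lognormally; centroids are clamped to the landscape and ranges clipped to
it, mimicking a continental edge.

Default study conditions (chosen once as a realistic desk-scale clade, and
used by the tests and the acceptance script):

| parameter | default | reading |
|---|---|---|
| `n_tips` | 200 | a mid-sized clade (hundreds of tips) |
| `birth_rate` | 1.0 /time | time unit ≈ waiting time to speciation |
| `death_rate` | 0.2 /time | modest background extinction |
| `bm_rate` | 0.1 /time | trait SD ≈ 0.8 over a tree depth of ~6 |
| `speciation_effect` | 0 | neutral unless a power scenario asks otherwise |
| `landscape_extent` | 100 × 100 | abstract units |
| `range_area_log_mean/sd` | log 30 / 1.0 | right-skewed areas, median 0.3% of landscape |
| `centroid_bm_rate` | 25 | relatives cluster at ~landscape/8 scale |

What the generator does **not** emulate: real coastlines and climate,
range-shape complexity (real ranges are ragged multipolygons), taxonomic
error, spatially varying diversification, or extinction-rate dependence on
density. Passing tests therefore demonstrate correctness of the statistics
and calibration of the test under a clean Brownian world — not that any
empirical clade behaves this way.

## Operating characteristics and a caveat

At the default conditions the test suite measures (at fixed seeds):

* type-I error of ES-sim at `alpha = 0.05` on Brownian-neutral traits,
  100-tip trees, 100 null simulations, 500 replicates — required to land
  in [0.03, 0.07];
* power rising monotonically in `beta` over {0, 0.5, 1, 2} (100 replicates
  each);
* ensemble behaviour under the neutral generator across 100 topologies:
  slopes of both signs and a fraction significant near `alpha`.

One structural caveat surfaced while building those tests: clade density is
not an arbitrary trait. Because `CD_i` sums covariance-weighted overlaps,
it partially tracks `rowSums(C)` — how much shared history a tip has with
the rest of the clade — and `rowSums(C)` correlates positively with
`lambda_DR` on any tree (tips inside recent radiations score high on both).
With sparse, heavy-tailed overlap matrices the geography term dominates and
the residual coupling is weak (per-topology correlations around 0.1), but
with dense, homogeneous sympatry it can inflate the observed correlation
relative to the Brownian null, making the test anticonservative. A
Brownian-neutral trait run through the same ensemble is the clean control
and calibrates at the nominal level.

## Numerical and procedural choices

* Quantiles use the linear-interpolation rule (`stats::quantile`, type 7);
  whiskers are Tukey's (most extreme point within 1.5 IQR of the nearer
  quartile).
* The top decile selects `ceiling(0.10 n)` species; ties at the cutoff
  widen the selection with a warning rather than an arbitrary drop.
* Log-scale distribution summaries exclude exact-zero overlaps (allopatric
  pairs) and flag an all-zero overlap set instead of crashing.
* Alignment between geography and tree (`align_species()`) reports dropped
  species on both sides; species without geography simply do not enter the
  statistic (there is no principled imputation for them).
* The pipeline (`run_all()`) stamps every table with a deterministic run id
  hashed from the analysis-relevant configuration, writes its manifest even
  on partial failure, and reruns byte-identically under a fixed seed.
* Problem sizes in the test suite (trees ≤ 200 tips, 100-topology
  ensembles, 500-replicate calibrations) are the package's chosen
  desk-scale study conditions; the same functions run unchanged on larger
  empirical datasets.

## Known limitations

* Shapefile input is not supported; convert to GeoJSON first.
* Ring repair handles proper crossings (figure-eights); exotic
  degeneracies (overlapping collinear edges) pass through unrepaired.
* The projection treats boundary segments as straight in projected space;
  densify very coarse polygons before projecting if 0.1% area accuracy
  matters.
* `fit_bm()` inverts the covariance directly, which is fine to a few
  thousand tips but not for trees of 10⁵ tips.
* ES-sim tests association, not causation, and cannot separate
  speciation-rate effects from extinction-rate effects.
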