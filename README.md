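# cladedensity

Tools for asking whether crowding by close relatives slows speciation.

Diversity-dependent diversification — the idea that speciation rates
decline as a region fills with competing species — is usually tested with
clade-level summaries that ignore *where* species actually live. This
package implements a species-level alternative built from two standard
ingredients, range polygons and a dated phylogeny:

* **Clade density.** For species *i* in a higher taxon,

  `CD_i = Σ_{j≠i} O_ij · C_ij`

  where `O_ij` is the area of overlap between the ranges of species *i*
  and *j* (in km² after equal-area projection) and `C_ij` is the
  phylogenetic variance–covariance — the depth of the pair's most recent
  common ancestor, i.e. their shared evolutionary time. Allopatric species
  score zero; species sympatric with many close relatives score high.
* **Tip speciation rates.** The inverse equal-splits statistic
  `λDR_i = 1 / Σ_j l_j 2^{-(j-1)}` over the root-to-tip branches
  (pendant edge first), computed on the full tree and only then subset to
  the species with geographic data.
* **ES-sim.** A semi-parametric test of association between a tip trait
  (here clade density) and `λDR`: the observed Pearson correlation is
  compared against correlations from traits simulated under Brownian
  motion fitted to the data on the same tree,
  `p = (1 + #{|ρ_k| ≥ |ρ_obs|}) / (n_sim + 1)`. A topology-ensemble
  wrapper repeats everything across alternative trees to propagate
  phylogenetic uncertainty.

Because range intersections need exact areas and no GEOS binding is
assumed, the package ships its own exact polygon engine (signed convex
decomposition: ear-clipping, Sutherland–Hodgman clipping,
inclusion–exclusion unions), GeoJSON I/O with IUCN-style presence/origin
filtering, a Lambert cylindrical equal-area projection, and a synthetic
generator (birth–death trees with optionally trait-dependent speciation,
plus phylogenetically autocorrelated ranges) so the whole pipeline is
testable with known ground truth.

## Worked example

```r
library(cladedensity)

cfg    <- scenario_config(n_tips = 80, seed = 11)   # synthetic clade
sim    <- simulate_tree(cfg)                        # dated tree + true traits
ranges <- simulate_ranges(sim, cfg)                 # autocorrelated ranges

O  <- compute_overlap_matrix(ranges)                # pairwise overlap areas
al <- align_species(O, phylo_vcv(sim$tree))         # shared species, one order
cd <- clade_density(al$overlap, al$vcv)

summarize_density(cd)
#>  min lower_whisker      q25   median      q75 upper_whisker      max  n
#>    0             0 42.66402 119.3565 247.2998      546.9624 938.2672 80

head(top_decile(cd))
#> [1] "s0079" "s0008" "s0062" "s0066" "s0074" "s0032"

essim(sim$tree, setNames(cd$clade_density, cd$species), n_sim = 100, seed = 1)
#> ES-sim: rho = 0.1754, slope = 0.0001383, p = 0.3267 (100 null sims, 80 species)
```

The summary shows the typical right-skewed clade-density distribution
(median 119 area·time units, a long upper tail, some fully allopatric
species at 0). `top_decile()` returns the `ceiling(0.1·n)` species with the
highest values — the candidates for mapping where crowding concentrates.
The ES-sim result says the observed trait–rate correlation (0.175) is
unremarkable against 100 Brownian null simulations (p ≈ 0.33): in this
neutral simulation, clade density does not predict speciation rate, as it
should not.

For real data the entry points are `load_ranges()` (GeoJSON, with
uncertain/introduced features filtered) → `project_equal_area()` →
`compute_overlap_matrix()`, and `read_newick()` for single trees or
one-per-line topology ensembles; `run_ensemble()` or the `run_all()`
pipeline (YAML config, deterministic run id, manifest, TSV/GeoJSON
outputs) take it from there. A thin CLI lives in
`inst/scripts/cladedensity-pipeline.R`.

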