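Package: cladedensity
Title: Clade Density, Tip Speciation Rates and Simulation Tests of
    Diversity-Dependent Diversification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes clade density, a per-species measure of phylogenetically
    weighted sympatry: the sum of pairwise range-overlap areas with the other
    members of a higher taxon, each weighted by the pair's phylogenetic
    covariance (shared root-path length). Provides exact polygon geometry for
    range areas and pairwise overlap matrices (with equal-area projection of
    longitude/latitude ranges and IUCN-style presence/origin filtering),
    per-tip equal-splits speciation-rate estimates (lambda-DR), the ES-sim
    semi-parametric test of trait-dependent speciation with a Brownian-motion
    simulation null, topology-ensemble wrappers for phylogenetic uncertainty,
    and a synthetic-data generator (birth-death trees with optional
    trait-dependent speciation, and geographically autocorrelated ranges) so
    the whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
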