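# Ground-truth properties of the synthetic tree / trait / range generator.

test_that("configs are validated", {
  expect_error(scenario_config(n_tips = 2), "n_tips")
  expect_error(scenario_config(birth_rate = 0.1, death_rate = 0.2), "rates")
  expect_error(scenario_config(landscape_extent = c(-1, 5)), "landscape")
})

test_that("tree simulation conditions on tip count with positive lengths", {
  cfg <- scenario_config(n_tips = 3, death_rate = 0, seed = 101)
  sim <- simulate_tree(cfg)
  expect_length(sim$tree$tip.label, 3)

  for (s in c(1, 2)) {
    cfg2 <- scenario_config(n_tips = 60, seed = s)
    sim2 <- simulate_tree(cfg2)
    expect_length(sim2$tree$tip.label, 60)
    expect_true(all(sim2$tree$edge.length > 0))
    expect_true(ape::is.binary(sim2$tree))
    expect_true(ape::is.rooted(sim2$tree))
    expect_true(ape::is.ultrametric(sim2$tree, tol = 1e-8))
    expect_setequal(names(sim2$traits), sim2$tree$tip.label)
  }
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- scenario_config(n_tips = 20, seed = 77)
  s1 <- simulate_tree(cfg); s2 <- simulate_tree(cfg)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_identical(s1$traits, s2$traits)

  r1 <- simulate_ranges(s1, cfg); r2 <- simulate_ranges(s2, cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_ranges_geojson(r1, f1); write_ranges_geojson(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("neutral traits are exactly Brownian: standardized moments match", {
  # x ~ N(0, sigma2 * C) on each realized tree, so z = L^-T x / sigma should
  # be iid standard normal; pool z over replicates and check moments
  sigma2 <- 0.1
  zs <- c()
  for (k in 1:300) {
    cfg <- scenario_config(n_tips = 8, bm_rate = sigma2, seed = 3000 + k)
    sim <- simulate_tree(cfg)
    C <- phylo_vcv(sim$tree)
    z <- backsolve(chol(C), sim$traits[rownames(C)], transpose = TRUE) /
      sqrt(sigma2)
    zs <- c(zs, z)
  }
  expect_equal(mean(zs), 0, tolerance = 0.07)      # SE ~ 0.02
  expect_equal(mean(zs^2), 1, tolerance = 0.12)    # SE ~ 0.03
})

test_that("strong trait-dependent speciation couples trait and lambda-DR", {
  pos <- 0L
  for (k in 1:100) {
    cfg <- scenario_config(n_tips = 200, trait_model = "speciation_dependent",
                           speciation_effect = 2, seed = 4000 + k)
    sim <- simulate_tree(cfg)
    rates <- dr_statistic(sim$tree)
    lam <- stats::setNames(rates$lambda_dr, rates$species)
    if (cor(sim$traits[names(lam)], lam) > 0) pos <- pos + 1L
  }
  expect_gt(pos, 50)   # positive correlation in the majority of replicates
})

test_that("zero centroid rate gives concentric ranges with min-area overlaps", {
  cfg <- scenario_config(n_tips = 10, centroid_bm_rate = 0, seed = 111)
  sim <- simulate_tree(cfg)
  O <- compute_overlap_matrix(simulate_ranges(sim, cfg))
  mins <- outer(diag(O), diag(O), pmin)
  off <- upper.tri(O)
  expect_equal(O[off], mins[off], tolerance = 1e-9)
})

test_that("huge centroid dispersal drives off-diagonal overlap to zero", {
  # dispersal huge relative to range sizes, landscape wide enough that the
  # boundary clamp does not pile centroids onto the edges
  cfg <- scenario_config(n_tips = 25, centroid_bm_rate = 1e6,
                         landscape_extent = c(1e5, 1e5),
                         range_area_log_mean = log(0.5), seed = 113)
  sim <- simulate_tree(cfg)
  O <- compute_overlap_matrix(simulate_ranges(sim, cfg))
  off <- O[upper.tri(O)]
  expect_lt(mean(off > 0), 0.05)
  expect_lt(sum(off) / sum(diag(O)), 0.05)
})

test_that("range areas are positive and lognormal draws are clipped sanely", {
  cfg <- scenario_config(n_tips = 40, seed = 127)
  sim <- simulate_tree(cfg)
  rng <- simulate_ranges(sim, cfg)
  a <- range_areas(rng)
  expect_true(all(a > 0))
  expect_true(all(a <= prod(cfg$landscape_extent)))
})

test_that("concentric disc ranges nest exactly like squares", {
  cfg <- scenario_config(n_tips = 12, range_shape = "disc",
                         centroid_bm_rate = 0, seed = 131)
  sim <- simulate_tree(cfg)
  O <- compute_overlap_matrix(simulate_ranges(sim, cfg))
  mins <- outer(diag(O), diag(O), pmin)
  off <- upper.tri(O)
  expect_equal(O[off], mins[off], tolerance = 1e-9)
  expect_true(all(diag(O) > 0))
})

test_that("fixtures round-trip and inconsistent inputs fail loudly", {
  cfg <- scenario_config(n_tips = 5, artifact_fraction = 0.4, seed = 137)
  sim <- simulate_tree(cfg)
  rng <- simulate_ranges(sim, cfg)
  out <- tempfile()
  paths <- write_fixture(sim, rng, out)
  expect_true(all(file.exists(paths)))

  tr <- read_newick(paths[["tree"]])
  expect_setequal(tr$tip.label, sim$tree$tip.label)
  back <- load_ranges(paths[["ranges"]], projection = "planar")
  expect_setequal(back$species, rng$species)
  expect_gte(back$report$n_dropped, 1)   # injected artifacts filtered out
  expect_equal(range_areas(back)[rng$species], range_areas(rng),
               tolerance = 1e-9)
  O <- compute_overlap_matrix(back)
  expect_identical(dim(O), c(5L, 5L))
  traits <- utils::read.delim(paths[["traits"]])
  expect_setequal(traits$species, sim$tree$tip.label)

  bad <- rng
  names(bad$geoms)[1] <- "intruder"
  bad$species <- names(bad$geoms)
  expect_error(write_fixture(sim, bad, tempfile()), "intruder")
  empty <- rng
  empty$geoms <- list(); empty$species <- character(0)
  expect_error(write_fixture(sim, empty, tempfile()), "empty species set")
})
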