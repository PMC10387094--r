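# Brownian-motion fitting and the ES-sim association test.

test_that("fit_bm recovers closed forms", {
  C <- phylo_vcv(random_labelled_tree(6))
  f <- fit_bm(C, rep(3.2, 6))
  expect_equal(f$ancestral_mean, 3.2)
  expect_equal(f$sigma2, 0, tolerance = 1e-12)

  # star tree: GLS collapses to the arithmetic mean and ML variance / T
  T_depth <- 2
  star <- diag(6) * T_depth
  dimnames(star) <- list(letters[1:6], letters[1:6])
  set.seed(3)
  x <- rnorm(6)
  f2 <- fit_bm(star, x)
  expect_equal(f2$ancestral_mean, mean(x))
  expect_equal(f2$sigma2, sum((x - mean(x))^2) / (6 * T_depth))
})

test_that("fit_bm is calibrated on traits simulated with known rate", {
  set.seed(5)
  tr <- ape::rcoal(100)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  C <- phylo_vcv(tr)
  s2 <- replicate(200, {
    x <- as.numeric(MASS::mvrnorm(1, mu = rep(0, 100), Sigma = C))
    fit_bm(C, stats::setNames(x, rownames(C)))$sigma2
  })
  expect_equal(mean(s2), 1, tolerance = 0.05)
})

test_that("a trait identical to log lambda-DR gives rho 1 and minimal p", {
  set.seed(7)
  tr <- random_labelled_tree(40)
  rates <- dr_statistic(tr)
  trait <- stats::setNames(log(rates$lambda_dr), rates$species)
  res <- essim(tr, trait, rates = rates, n_sim = 100, seed = 2,
               trait_transform = "identity")
  expect_equal(res$rho, 1)
  expect_equal(res$p, 1 / 101)
})

test_that("degenerate inputs raise explicit errors", {
  tr <- random_labelled_tree(10)
  const <- stats::setNames(rep(1, 10), tr$tip.label)
  expect_error(essim(tr, const), "constant trait")
  tr3 <- stats::setNames(rnorm(10), tr$tip.label)
  expect_error(essim(tr, tr3, n_sim = 0), "n_sim")
  expect_error(essim(tr, stats::setNames(rnorm(3), tr$tip.label[1:3])),
               "at least 4")
})

test_that("p-values live on the k/(n_sim+1) grid and runs are reproducible", {
  set.seed(11)
  tr <- random_labelled_tree(30)
  trait <- stats::setNames(exp(rnorm(30)), tr$tip.label)
  expect_error(essim(tr, trait - 5), "non-negative")
  r1 <- essim(tr, trait, n_sim = 100, seed = 5)
  r2 <- essim(tr, trait, n_sim = 100, seed = 5)
  expect_identical(r1$rho, r2$rho)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$null_rho, r2$null_rho)
  expect_true(r1$p %in% ((1:101) / 101))
  expect_true(all(abs(r1$null_rho) <= 1))
  expect_gt(r1$p, 0)
})

test_that("rho is affine-invariant and the slope rescales as 1/a", {
  set.seed(13)
  tr <- random_labelled_tree(25)
  trait <- stats::setNames(exp(rnorm(25)), tr$tip.label)
  r1 <- essim(tr, trait, n_sim = 50, seed = 3, trait_transform = "identity")
  a <- 7.5
  r2 <- essim(tr, a * trait + 2, n_sim = 50, seed = 3,
              trait_transform = "identity")
  expect_equal(r2$rho, r1$rho, tolerance = 1e-12)
  expect_equal(r2$p, r1$p)
  expect_equal(r2$slope, r1$slope / a, tolerance = 1e-12)
})

test_that("an ensemble of one tree matches a single essim call", {
  cfg <- scenario_config(n_tips = 30, seed = 19)
  sim <- simulate_tree(cfg)
  O <- compute_overlap_matrix(simulate_ranges(sim, cfg))
  single_al <- align_species(O, phylo_vcv(sim$tree))
  cd <- clade_density(single_al$overlap, single_al$vcv)
  single <- essim(sim$tree, stats::setNames(cd$clade_density, cd$species),
                  rates = dr_statistic(sim$tree), n_sim = 50, seed = 4)
  ens <- run_ensemble(list(sim$tree), O, n_sim = 50, seed = 4)
  expect_equal(ens$records$rho, single$rho)
  expect_equal(ens$records$slope, single$slope)
  expect_equal(ens$records$p, single$p)
})

test_that("a repeated topology yields identical ensemble records", {
  cfg <- scenario_config(n_tips = 25, seed = 23)
  sim <- simulate_tree(cfg)
  O <- compute_overlap_matrix(simulate_ranges(sim, cfg))
  ens <- run_ensemble(rep(list(sim$tree), 5), O, n_sim = 50, seed = 6)
  expect_equal(nrow(ens$records), 5)
  expect_length(unique(ens$records$rho), 1)
  expect_length(unique(ens$records$p), 1)
  expect_length(unique(ens$records$slope), 1)
})

test_that("per-topology failures are skipped with a warning, not fatal", {
  cfg <- scenario_config(n_tips = 20, seed = 29)
  sim <- simulate_tree(cfg)
  O <- compute_overlap_matrix(simulate_ranges(sim, cfg))
  bad <- sim$tree
  bad$tip.label <- paste0("zz_", bad$tip.label)   # shares no species
  expect_warning(ens <- run_ensemble(list(sim$tree, bad), O, n_sim = 20, seed = 1),
                 "skipped")
  expect_equal(sum(is.na(ens$records$p)), 1)
  expect_equal(ens$summary$n_ok, 1)
})
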