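# The clade-density statistic and its summaries.

test_that("align_species intersects and reports dropped species", {
  O <- random_overlap_matrix(3)
  dimnames(O) <- list(c("B", "C", "D"), c("B", "C", "D"))
  C <- phylo_vcv(read_newick(text = "((A:0.5,B:0.5):0.5,C:1);"))
  al <- align_species(O, C)
  expect_setequal(al$species, c("B", "C"))
  expect_identical(al$dropped_geography, "A")
  expect_identical(al$dropped_tree, "D")
  expect_identical(rownames(al$overlap), rownames(al$vcv))
  expect_error(align_species(O[3, 3, drop = FALSE], C), "no species shared")
})

test_that("clade density reproduces the single-term worked example", {
  C <- phylo_vcv(read_newick(text = "((A:0.5,B:0.5):0.5,C:1);"))
  O <- matrix(0, 3, 3, dimnames = dimnames(C))
  diag(O) <- 5
  O["A", "B"] <- O["B", "A"] <- 2.0
  cd <- clade_density(O, C)
  expect_equal(stats::setNames(cd$clade_density, cd$species),
               c(A = 1.0, B = 1.0, C = 0))
  # include_self adds O_ii * C_ii
  cd_self <- clade_density(O, C, include_self = TRUE)
  expect_equal(cd_self$clade_density, cd$clade_density + unname(5 * diag(C)))
})

test_that("matrix implementation equals the brute-force double loop", {
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(4:30, 1)
    tr <- random_labelled_tree(n)
    C <- phylo_vcv(tr)
    O <- random_overlap_matrix(n)
    dimnames(O) <- dimnames(C)
    for (self in c(FALSE, TRUE)) {
      cd <- clade_density(O, C, include_self = self)
      oracle <- cd_brute_force(O, C, include_self = self)
      expect_equal(stats::setNames(cd$clade_density, cd$species), oracle,
                   tolerance = 1e-9)
    }
  }
})

test_that("clade density is invariant to species reordering", {
  set.seed(67)
  tr <- random_labelled_tree(10)
  C <- phylo_vcv(tr)
  O <- random_overlap_matrix(10)
  dimnames(O) <- dimnames(C)
  cd1 <- clade_density(O, C)
  perm <- sample(10)
  cd2 <- clade_density(O[perm, perm], C[perm, perm])
  expect_equal(stats::setNames(cd2$clade_density, cd2$species)[cd1$species],
               stats::setNames(cd1$clade_density, cd1$species))
})

test_that("clade density is bilinear and monotone in overlaps", {
  set.seed(71)
  tr <- random_labelled_tree(8)
  C <- phylo_vcv(tr)
  O <- random_overlap_matrix(8)
  dimnames(O) <- dimnames(C)
  cd <- clade_density(O, C)$clade_density
  expect_equal(clade_density(O * 3, C)$clade_density, 3 * cd)
  expect_equal(clade_density(O, C * 0.5)$clade_density, 0.5 * cd)
  expect_equal(clade_density(O, C, area_scale = 10)$clade_density, cd / 10)

  # bump one off-diagonal overlap: only the two species involved can change,
  # and never downward
  i <- 2; j <- 5
  O2 <- O
  O2[i, j] <- O2[j, i] <- O2[i, j] + 1
  cd2 <- clade_density(O2, C)$clade_density
  expect_gte(cd2[i], cd[i])
  expect_gte(cd2[j], cd[j])
  expect_equal(cd2[-c(i, j)], cd[-c(i, j)])
})

test_that("allopatric clades have zero clade density everywhere", {
  set.seed(73)
  tr <- random_labelled_tree(12)
  C <- phylo_vcv(tr)
  O <- matrix(0, 12, 12, dimnames = dimnames(C))
  diag(O) <- rlnorm(12, 3, 1)
  expect_equal(clade_density(O, C)$clade_density, rep(0, 12))
})

test_that("misaligned inputs are rejected", {
  C <- phylo_vcv(random_labelled_tree(5))
  O <- random_overlap_matrix(5)
  expect_error(clade_density(O, C), "align")
})

test_that("top decile takes ceiling(n/10) species and widens only on ties", {
  tab <- data.frame(species = sprintf("s%02d", 1:10),
                    clade_density = 10:1)
  expect_identical(as.character(top_decile(tab)), "s01")

  tab25 <- data.frame(species = sprintf("s%02d", 1:25),
                      clade_density = 25:1)
  expect_length(top_decile(tab25), 3)   # ceiling(2.5)

  ties <- data.frame(species = letters[1:6], clade_density = rep(4, 6))
  expect_warning(sel <- top_decile(ties), "ties")
  expect_length(sel, 6)
})

test_that("density summaries use type-7 quantiles and Tukey whiskers", {
  s <- summarize_density(c(0, 1, 2, 3, 4))
  expect_equal(s$median, 2); expect_equal(s$q25, 1); expect_equal(s$q75, 3)

  s1 <- summarize_density(7.5)
  expect_true(all(unlist(s1[1:7]) == 7.5))

  x <- c(rep(0, 19), 100)
  s2 <- summarize_density(x)
  expect_equal(s2$upper_whisker, 0)   # 100 is beyond Q3 + 1.5 IQR
  expect_equal(s2$max, 100)
  expect_true(with(s2, min <= q25 && q25 <= median && median <= q75 && q75 <= max))
})

test_that("top-decile GeoJSON export round-trips geometry and density", {
  rings <- list(a = square_ring(0, 0, 2), b = square_ring(5, 5, 1),
                c = square_ring(9, 9, 3))
  rs <- make_range_set(rings)
  tab <- data.frame(species = c("a", "b", "c"), clade_density = c(9, 1, 5))
  f <- tempfile(fileext = ".geojson")
  export_top_decile_geo(rs, c("a", "c"), f, table = tab)
  back <- load_ranges(f, filters = NULL, projection = "planar")
  expect_setequal(back$species, c("a", "c"))
  expect_equal(range_areas(back)[["a"]], 4, tolerance = 1e-9)
  gj <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(gj$features[[1]]$properties$clade_density, 9)

  # empty selection is a valid, empty collection
  f2 <- tempfile(fileext = ".geojson")
  export_top_decile_geo(rs, character(0), f2)
  gj2 <- jsonlite::fromJSON(f2, simplifyVector = FALSE)
  expect_length(gj2$features, 0)

  expect_error(export_top_decile_geo(rs, "zz", tempfile()), "zz")
})
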