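# Independent oracles and small fixture builders shared across tests.

square_ring <- function(x0, y0, side) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side))
}

# range_set built directly from rings: geoms = named list, each element a
# list of rings (one polygon per ring, no holes)
make_range_set <- function(rings, projection = "planar") {
  geoms <- lapply(rings, function(rs) {
    if (is.matrix(rs)) rs <- list(rs)
    lapply(rs, function(r) list(outer = r, holes = list()))
  })
  features <- data.frame(species = names(rings), presence = "extant",
                         origin = "native", kept = TRUE,
                         stringsAsFactors = FALSE)
  cladedensity:::new_range_set(geoms, features, projection)
}

# Monte-Carlo area oracle: even-odd point membership evaluated per ring with
# pracma::inpolygon (independent of the package's geometry code)
mc_in_multipolygon <- function(px, py, mp) {
  inside <- rep(FALSE, length(px))
  for (poly in mp) {
    o <- cladedensity:::ring_open(poly$outer)
    hit <- pracma::inpolygon(px, py, o[, 1], o[, 2], boundary = TRUE)
    for (h in poly$holes) {
      hh <- cladedensity:::ring_open(h)
      hit <- hit & !pracma::inpolygon(px, py, hh[, 1], hh[, 2], boundary = FALSE)
    }
    inside <- inside | hit
  }
  inside
}

mc_intersection_area <- function(mp_a, mp_b, xlim, ylim, n = 2e5, seed = 1) {
  set.seed(seed)
  px <- runif(n, xlim[1], xlim[2])
  py <- runif(n, ylim[1], ylim[2])
  frac <- mean(mc_in_multipolygon(px, py, mp_a) & mc_in_multipolygon(px, py, mp_b))
  frac * diff(xlim) * diff(ylim)
}

# VCV oracle: shared root-path length computed from explicit node paths
vcv_path_oracle <- function(tree) {
  n <- length(tree$tip.label)
  elen <- numeric(n + tree$Nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  paths <- lapply(seq_len(n), function(i) ape::nodepath(tree, from = n + 1L, to = i))
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in i:n) {
      shared <- intersect(paths[[i]][-1], paths[[j]][-1])
      C[i, j] <- C[j, i] <- sum(elen[shared])
    }
  }
  C
}

# equal-splits oracle: top-down recursion halving the weight at every split
es_recursive_oracle <- function(tree) {
  n <- length(tree$tip.label)
  elen <- numeric(n + tree$Nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  es <- numeric(n)
  walk <- function(node, acc, depth_splits) {
    if (node <= n) {
      es[node] <<- acc
      return(invisible())
    }
    for (ch in kids[[as.character(node)]]) {
      # contribution of edge ch to every descendant tip gets halved at each
      # later split; accumulate by carrying acc/2 downward past each node
      walk(ch, acc / 2 + elen[ch], depth_splits + 1L)
    }
  }
  # root: children edges carry full weight (pendant-first indexing)
  for (ch in kids[[as.character(n + 1L)]]) walk(ch, elen[ch], 1L)
  stats::setNames(es, tree$tip.label)
}

# brute-force clade density double loop
cd_brute_force <- function(O, C, include_self = FALSE) {
  n <- nrow(O)
  cd <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j && !include_self) next
      cd[i] <- cd[i] + O[i, j] * C[i, j]
    }
  }
  stats::setNames(cd, rownames(O))
}

# random symmetric overlap matrix with valid invariants (O_ij <= min areas)
random_overlap_matrix <- function(n, sparsity = 0.5) {
  areas <- rlnorm(n, 3, 1)
  O <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (runif(1) < sparsity) {
        O[i, j] <- O[j, i] <- runif(1) * min(areas[i], areas[j])
      }
    }
  }
  diag(O) <- areas
  sp <- sprintf("s%03d", seq_len(n))
  dimnames(O) <- list(sp, sp)
  O
}

random_labelled_tree <- function(n) {
  tr <- ape::rcoal(n)
  tr$tip.label <- sprintf("s%03d", sample.int(n))
  tr
}

# boundary of a spherical cap (dense lon/lat polygon) plus its exact area
spherical_cap <- function(lon0, lat0, ang_deg, m = 720, radius = 6371.0072) {
  th <- ang_deg * pi / 180
  phi0 <- lat0 * pi / 180; lam0 <- lon0 * pi / 180
  # rotate a circle of colatitude th around the pole onto (lon0, lat0)
  t <- 2 * pi * (seq_len(m) - 1) / m
  x <- sin(th) * cos(t); y <- sin(th) * sin(t); z <- rep(cos(th), m)
  # rotate pole to latitude phi0 (about y axis), then to longitude lam0 (about z)
  x1 <- x * sin(phi0) + z * cos(phi0)
  z1 <- -x * cos(phi0) + z * sin(phi0)
  y1 <- y
  x2 <- x1 * cos(lam0) - y1 * sin(lam0)
  y2 <- x1 * sin(lam0) + y1 * cos(lam0)
  lon <- atan2(y2, x2) * 180 / pi
  lat <- asin(pmin(pmax(z1, -1), 1)) * 180 / pi
  list(ring = cbind(lon, lat), area = 2 * pi * radius^2 * (1 - cos(th)))
}
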