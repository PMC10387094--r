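# Synthetic trees, traits and geographically autocorrelated ranges.
#
# The generator emulates the statistical structure of real macroevolutionary
# range data — clades of hundreds of tips, right-skewed lognormal range
# sizes, range placement autocorrelated on the phylogeny so close relatives
# overlap more — with known ground truth, so every downstream statistic is
# testable without external downloads.

#' Scenario configuration for the synthetic generator
#'
#' @param n_tips number of extant tips to condition on (>= 3).
#' @param birth_rate baseline speciation rate lambda0 (events per unit time).
#' @param death_rate extinction rate mu (< birth_rate).
#' @param trait_model `"bm_neutral"` (trait evolves by Brownian motion,
#'   no feedback) or `"speciation_dependent"` (per-lineage speciation rate
#'   `lambda0 * exp(beta * x)`).
#' @param bm_rate Brownian-motion trait variance per unit time (sigma^2).
#' @param speciation_effect beta, the exponent multiplier linking trait to
#'   speciation rate (dimensionless; 0 recovers the neutral model).
#' @param landscape_extent width and height of the landscape (area units).
#' @param range_area_log_mean,range_area_log_sd lognormal parameters of
#'   range areas (log area units^2).
#' @param centroid_bm_rate spatial variance per unit time of the Brownian
#'   motion that places range centroids on the tree.
#' @param range_shape `"square"` (axis-aligned; exact analytic overlaps) or
#'   `"disc"` (regular 64-gon of matching area).
#' @param artifact_fraction fraction of species receiving an extra
#'   introduced/uncertain feature, for filter testing.
#' @param seed integer seed; every generator draw derives from it.
#' @param max_retries bound on restarts after whole-clade extinction.
#' @return validated `scenario_config` list.
#' @export
scenario_config <- function(n_tips = 200,
                            birth_rate = 1.0,
                            death_rate = 0.2,
                            trait_model = c("bm_neutral", "speciation_dependent"),
                            bm_rate = 0.1,
                            speciation_effect = 0,
                            landscape_extent = c(100, 100),
                            range_area_log_mean = log(30),
                            range_area_log_sd = 1.0,
                            centroid_bm_rate = 25,
                            range_shape = c("square", "disc"),
                            artifact_fraction = 0,
                            seed = 42L,
                            max_retries = 100L) {
  trait_model <- match.arg(trait_model)
  range_shape <- match.arg(range_shape)
  if (n_tips < 3) stop("n_tips must be at least 3")
  if (birth_rate <= death_rate || death_rate < 0)
    stop("rates must satisfy birth_rate > death_rate >= 0")
  if (bm_rate < 0 || centroid_bm_rate < 0) stop("rates must be non-negative")
  if (length(landscape_extent) != 2 || any(landscape_extent <= 0))
    stop("landscape_extent must be two positive numbers")
  if (artifact_fraction < 0 || artifact_fraction > 1)
    stop("artifact_fraction must be in [0, 1]")
  structure(list(n_tips = as.integer(n_tips), birth_rate = birth_rate,
                 death_rate = death_rate, trait_model = trait_model,
                 bm_rate = bm_rate, speciation_effect = speciation_effect,
                 landscape_extent = landscape_extent,
                 range_area_log_mean = range_area_log_mean,
                 range_area_log_sd = range_area_log_sd,
                 centroid_bm_rate = centroid_bm_rate,
                 range_shape = range_shape,
                 artifact_fraction = artifact_fraction,
                 seed = as.integer(seed),
                 max_retries = as.integer(max_retries)),
            class = "scenario_config")
}

#' Simulate a birth-death tree with a co-evolving trait
#'
#' Gillespie simulation conditioned on reaching `n_tips` extant lineages
#' (whole-clade extinctions trigger a bounded number of restarts).  A trait
#' diffuses by Brownian motion along every lineage; under
#' `trait_model = "speciation_dependent"` each lineage speciates at rate
#' `lambda0 * exp(beta * x)`, with rates held constant between events and
#' refreshed from the traits at every event time (exact when beta = 0).
#' Extinct lineages are pruned, so the returned tree has exactly `n_tips`
#' extant, contemporaneous tips with strictly positive branch lengths.
#'
#' @param config a [scenario_config()].
#' @return list of class `sim_tree`: `tree` (phylo), `traits` (named by
#'   tip), `true_rate` (per-tip `lambda0 * exp(beta * x)`), `retries`.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  beta <- if (config$trait_model == "speciation_dependent")
    config$speciation_effect else 0
  for (attempt in seq_len(config$max_retries)) {
    out <- gillespie_once(config$n_tips, config$birth_rate, config$death_rate,
                          config$bm_rate, beta)
    if (!is.null(out)) {
      out$retries <- attempt - 1L
      class(out) <- "sim_tree"
      return(out)
    }
  }
  stop("whole-clade extinction in every attempt (", config$max_retries,
       " retries); raise birth_rate or max_retries")
}

# one forward pass; NULL on extinction before reaching n tips
gillespie_once <- function(n_tips, lambda0, mu, sigma2, beta) {
  ep <- character(0); ec <- character(0); el <- numeric(0)  # edge store
  node_ct <- 1L; tip_ct <- 0L; ext_ct <- 0L
  # active lineages
  par <- c("n1", "n1"); t0 <- c(0, 0); x <- c(0, 0)
  t <- 0
  repeat {
    nal <- length(par)
    rates <- lambda0 * exp(beta * x)
    B <- sum(rates); D <- nal * mu
    dt <- stats::rexp(1, B + D)
    # trait diffusion over the waiting interval
    x <- x + stats::rnorm(nal, 0, sqrt(sigma2 * dt))
    t <- t + dt
    if (stats::runif(1) < B / (B + D)) {
      i <- sample.int(nal, 1L, prob = rates)
      node_ct <- node_ct + 1L
      nd <- paste0("n", node_ct)
      ep <- c(ep, par[i]); ec <- c(ec, nd); el <- c(el, t - t0[i])
      par <- c(par[-i], nd, nd)
      t0 <- c(t0[-i], t, t)
      x <- c(x[-i], x[i], x[i])
      if (length(par) == n_tips) break
    } else {
      i <- sample.int(nal, 1L)
      ext_ct <- ext_ct + 1L
      tip <- paste0("x", ext_ct)
      ep <- c(ep, par[i]); ec <- c(ec, tip); el <- c(el, t - t0[i])
      par <- par[-i]; t0 <- t0[-i]; x <- x[-i]
      if (!length(par)) return(NULL)
    }
  }
  # stop inside the next waiting interval so pendant edges stay positive
  rates <- lambda0 * exp(beta * x)
  dt <- stats::rexp(1, sum(rates) + length(par) * mu) * stats::runif(1)
  x <- x + stats::rnorm(length(par), 0, sqrt(sigma2 * dt))
  present <- t + dt
  # species identity must not encode lineage birth order, or independently
  # simulated topologies on the same label set would share hidden structure
  tips <- sprintf("s%04d", sample.int(length(par)))
  ep <- c(ep, par); ec <- c(ec, tips); el <- c(el, present - t0)

  tree <- edges_to_phylo(ep, ec, el, root = "n1")
  if (ext_ct > 0) {
    tree <- ape::drop.tip(tree, paste0("x", seq_len(ext_ct)))
  }
  traits <- stats::setNames(x, tips)[tree$tip.label]
  list(tree = tree, traits = traits,
       true_rate = lambda0 * exp(beta * traits))
}

# assemble a phylo from a parent/child/length edge list via Newick text
edges_to_phylo <- function(parents, children, lengths, root) {
  kids <- split(seq_along(parents), parents)
  build <- function(node) {
    ks <- kids[[node]]
    if (is.null(ks)) return(node)
    inner <- vapply(ks, function(e) {
      paste0(build(children[e]), ":", sprintf("%.17g", lengths[e]))
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  ape::read.tree(text = paste0(build(root), ";"))
}

#' Simulate species ranges autocorrelated on the phylogeny
#'
#' Each tip receives a range (axis-aligned square by default, or a 64-gon
#' "disc") centred on a 2-D centroid simulated by Brownian motion on the
#' tree with rate `centroid_bm_rate` per axis from the landscape centre, so
#' closely related species sit near each other and overlap more.  Areas are
#' drawn lognormally; ranges are clipped to the landscape (centroids are
#' first clamped inside it, mimicking a continental boundary).
#'
#' @param sim a `sim_tree` (or a bare `phylo`).
#' @param config the [scenario_config()] used for the simulation.
#' @return a planar `range_set`; when `artifact_fraction > 0`, extra
#'   features flagged `introduced` / `uncertain` are attached for filter
#'   testing (excluded from the in-memory dissolved geometry).
#' @export
simulate_ranges <- function(sim, config) {
  stopifnot(inherits(config, "scenario_config"))
  tree <- if (inherits(sim, "sim_tree")) sim$tree else sim
  validate_tree(tree)
  set.seed(config$seed + 1L)
  tips <- tree$tip.label
  n <- length(tips)
  W <- config$landscape_extent[1]; H <- config$landscape_extent[2]

  C <- phylo_vcv(tree)[tips, tips]
  L <- chol(C)
  centre <- c(W / 2, H / 2)
  cxy <- sqrt(config$centroid_bm_rate) *
    cbind(crossprod(L, stats::rnorm(n)), crossprod(L, stats::rnorm(n)))
  cxy <- sweep(cxy, 2, centre, "+")
  cxy[, 1] <- pmin(pmax(cxy[, 1], 0), W)
  cxy[, 2] <- pmin(pmax(cxy[, 2], 0), H)
  areas <- stats::rlnorm(n, config$range_area_log_mean, config$range_area_log_sd)

  landscape <- rbind(c(0, 0), c(W, 0), c(W, H), c(0, H))
  make_range <- function(cx, cy, area) {
    ring <- if (config$range_shape == "square") {
      h <- sqrt(area) / 2
      rbind(c(cx - h, cy - h), c(cx + h, cy - h),
            c(cx + h, cy + h), c(cx - h, cy + h))
    } else {
      m <- 64L
      r <- sqrt(2 * area / (m * sin(2 * pi / m)))
      th <- 2 * pi * (seq_len(m) - 1) / m
      cbind(cx + r * cos(th), cy + r * sin(th))
    }
    clipped <- clip_convex(ring, landscape)
    if (nrow(clipped) < 3) stop("range entirely outside the landscape")
    list(outer = clipped, holes = list())
  }
  geoms <- lapply(seq_len(n), function(i) list(make_range(cxy[i, 1], cxy[i, 2], areas[i])))
  names(geoms) <- tips

  features <- data.frame(species = tips, presence = "extant",
                         origin = "native", kept = TRUE,
                         stringsAsFactors = FALSE)
  rs <- new_range_set(geoms, features, projection = "planar")
  if (config$artifact_fraction > 0) {
    n_art <- max(1L, round(config$artifact_fraction * n))
    pick <- sample(tips, n_art)
    rs$extra <- lapply(seq_along(pick), function(k) {
      sp <- pick[k]
      i <- match(sp, tips)
      shifted <- make_range(pmin(cxy[i, 1] + sqrt(areas[i]), W),
                            cxy[i, 2], areas[i])
      if (k %% 2 == 0) {
        list(species = sp, mp = list(shifted), presence = "extant",
             origin = "introduced")
      } else {
        list(species = sp, mp = list(shifted), presence = "uncertain",
             origin = "native")
      }
    })
  }
  rs
}

#' Write a synthetic fixture to disk
#'
#' Emits the Newick tree, the GeoJSON ranges (including any artifact
#' features), and a TSV of true tip traits and true speciation rates; the
#' files round-trip through [read_newick()] and [load_ranges()].
#'
#' @param sim a `sim_tree`.
#' @param ranges the matching `range_set`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_fixture <- function(sim, ranges, out_dir) {
  stopifnot(inherits(sim, "sim_tree"), inherits(ranges, "range_set"))
  if (!length(ranges$species)) stop("empty species set")
  mism <- c(setdiff(sim$tree$tip.label, ranges$species),
            setdiff(ranges$species, sim$tree$tip.label))
  if (length(mism))
    stop("species mismatch between tree and ranges: ",
         paste(unique(mism), collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tree = file.path(out_dir, "tree.nwk"),
             ranges = file.path(out_dir, "ranges.geojson"),
             traits = file.path(out_dir, "traits.tsv"))
  ape::write.tree(sim$tree, file = paths["tree"], digits = 15)
  write_ranges_geojson(ranges, paths["ranges"])
  utils::write.table(
    data.frame(species = names(sim$traits), trait = unname(sim$traits),
               true_rate = unname(sim$true_rate)),
    paths["traits"], sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}
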