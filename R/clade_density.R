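# Clade density: per-species phylogenetically weighted sympatry.

#' Align an overlap matrix and a phylogenetic covariance matrix
#'
#' Restricts both matrices to the species present in each (species without
#' geographic information, or without a place in the tree, are dropped and
#' reported) and puts rows and columns in one shared order.
#'
#' @param overlap species-by-species overlap matrix.
#' @param vcv species-by-species phylogenetic covariance matrix.
#' @return list: `overlap`, `vcv` (aligned), `species`, `dropped_geography`
#'   (in the tree but without ranges), `dropped_tree` (ranges but no tree).
#' @export
align_species <- function(overlap, vcv) {
  so <- rownames(overlap)
  sv <- rownames(vcv)
  if (is.null(so) || is.null(sv)) stop("both matrices need species dimnames")
  common <- so[so %in% sv]
  if (!length(common)) stop("no species shared between overlap matrix and tree")
  list(overlap = overlap[common, common, drop = FALSE],
       vcv = vcv[common, common, drop = FALSE],
       species = common,
       dropped_geography = setdiff(sv, so),
       dropped_tree = setdiff(so, sv))
}

#' Compute clade density for every species
#'
#' Clade density is the sum of a species' range-overlap areas with the other
#' members of its higher taxon, each weighted by the pair's phylogenetic
#' covariance (the depth of their most recent common ancestor):
#' `CD_i = sum_{j != i} O_ij * C_ij`.  Element-wise product of the two
#' matrices, then row sums — large values mean extensive sympatry with close
#' relatives.  Pass a different symmetric non-negative weight matrix (e.g.
#' [inv_patristic_weights()]) in place of the covariance for sensitivity
#' analyses.
#'
#' @param overlap,vcv matrices aligned with [align_species()].
#' @param include_self add the diagonal term `O_ii * C_ii` (off by default:
#'   a species is not its own neighbour).
#' @param area_scale divide overlap areas by this factor first (e.g. `1e6`
#'   to report per million km^2).
#' @return data frame `species`, `clade_density` (area x time units), with
#'   attributes `include_self` and `area_scale`.
#' @export
clade_density <- function(overlap, vcv, include_self = FALSE, area_scale = 1) {
  if (!identical(rownames(overlap), rownames(vcv)) ||
      !identical(colnames(overlap), colnames(vcv)) ||
      !identical(rownames(overlap), colnames(overlap)))
    stop("matrices are not aligned; call align_species() first")
  W <- (overlap / area_scale) * vcv
  cd <- rowSums(W)
  if (!include_self) cd <- cd - diag(W)
  out <- data.frame(species = rownames(overlap), clade_density = unname(cd),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "include_self") <- include_self
  attr(out, "area_scale") <- area_scale
  out
}

#' Inverse patristic distance weights
#'
#' Alternative sympatry weighting for sensitivity analysis: `1 / d_ij` with
#' `d_ij` the patristic distance between tips (diagonal set to 0).
#'
#' @param tree a `phylo`.
#' @return symmetric weight matrix.
#' @export
inv_patristic_weights <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  w <- 1 / d
  diag(w) <- 0
  w
}

#' Species in the top decile of clade density
#'
#' Returns the `ceiling(0.10 * n)` species with the highest clade density;
#' species tied with the cutoff value are all included (with a warning when
#' ties widen the selection).
#'
#' @param table output of [clade_density()].
#' @return character vector of species, highest density first; attribute
#'   `ties` flags a widened selection.
#' @export
top_decile <- function(table) {
  n <- nrow(table)
  if (n < 1) stop("empty clade-density table")
  k <- ceiling(0.10 * n)
  ord <- order(table$clade_density, decreasing = TRUE)
  cutoff <- table$clade_density[ord[k]]
  sel <- ord[table$clade_density[ord] >= cutoff]
  ties <- length(sel) > k
  if (ties)
    warning(sprintf("ties at the decile cutoff: %d species returned instead of %d",
                    length(sel), k))
  structure(table$species[sel], ties = ties)
}

#' Five-number-plus-whiskers summary of clade densities
#'
#' Quartiles use the linear-interpolation rule (`stats::quantile` type 7);
#' whiskers follow Tukey: the most extreme data point within 1.5 IQR of the
#' nearer quartile.
#'
#' @param table output of [clade_density()], or a numeric vector.
#' @return one-row data frame: `min`, `lower_whisker`, `q25`, `median`,
#'   `q75`, `upper_whisker`, `max`, `n`.
#' @export
summarize_density <- function(table) {
  x <- if (is.data.frame(table)) table$clade_density else as.numeric(table)
  if (!length(x)) stop("no clade-density values to summarize")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lw <- min(x[x >= q[1] - 1.5 * iqr])
  uw <- max(x[x <= q[3] + 1.5 * iqr])
  data.frame(min = min(x), lower_whisker = lw, q25 = q[1], median = q[2],
             q75 = q[3], upper_whisker = uw, max = max(x), n = length(x))
}

#' Export the ranges of selected species as a GeoJSON overlay
#'
#' Writes the geometries of the selected species (typically [top_decile()])
#' with their clade density attached as a feature property; map rendering is
#' left to external GIS tools.
#'
#' @param ranges the `range_set` holding the geometries.
#' @param species character vector of species to export.
#' @param path output GeoJSON file.
#' @param table optional [clade_density()] table supplying the property.
#' @return `path`, invisibly.  An empty selection writes an empty
#'   FeatureCollection, not an error.
#' @export
export_top_decile_geo <- function(ranges, species, path, table = NULL) {
  missing_geo <- setdiff(species, ranges$species)
  if (length(missing_geo))
    stop("species without geometry: ", paste(missing_geo, collapse = ", "))
  sub <- ranges
  sub$geoms <- ranges$geoms[species]
  sub$species <- species
  props <- NULL
  if (!is.null(table)) {
    props <- list(clade_density =
                    stats::setNames(table$clade_density, table$species))
  }
  write_ranges_geojson(sub, path, properties = props)
}
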