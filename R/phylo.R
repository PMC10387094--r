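# Tree I/O, phylogenetic variance-covariance matrices and lambda-DR tip
# speciation rates.  Trees are ape "phylo" objects throughout.

#' Read one or more Newick trees with validation
#'
#' Parses with \pkg{ape} and enforces the invariants the downstream
#' statistics need: labelled, unique tips; branch lengths present;
#' non-negative lengths (strictly positive unless `allow_zero = TRUE`).
#' A file with several trees (one per line) yields a `multiPhylo` ensemble.
#'
#' @param path path to a Newick file; alternatively pass `text`.
#' @param text Newick string(s), used when `path` is `NULL`.
#' @param allow_zero tolerate zero-length branches.
#' @return A `phylo`, or a `multiPhylo` when the input holds several trees.
#' @export
read_newick <- function(path = NULL, text = NULL, allow_zero = FALSE) {
  tr <- if (!is.null(path)) {
    if (!file.exists(path)) stop("tree file not found: ", path)
    ape::read.tree(path)
  } else {
    ape::read.tree(text = text)
  }
  if (is.null(tr)) stop("could not parse Newick input")
  if (inherits(tr, "multiPhylo")) {
    for (t in tr) validate_tree(t, allow_zero = allow_zero)
  } else {
    validate_tree(tr, allow_zero = allow_zero)
  }
  tr
}

#' Validate the tree invariants used across the package
#'
#' @param tree a `phylo`.
#' @param allow_zero tolerate zero-length branches.
#' @param require_binary reject polytomies.
#' @return `tree`, invisibly; otherwise an error naming the violation.
#' @export
validate_tree <- function(tree, allow_zero = FALSE, require_binary = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("tree has unlabeled tips")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths")
  if (!allow_zero && any(tree$edge.length == 0))
    stop("zero-length branches (pass allow_zero = TRUE to tolerate)")
  if (require_binary && !ape::is.binary(tree))
    stop("tree contains polytomies")
  invisible(tree)
}

#' Phylogenetic variance-covariance matrix
#'
#' `C[i, j]` is the depth (distance from the root) of the most recent common
#' ancestor of tips i and j — their shared evolutionary time under Brownian
#' motion; the diagonal holds root-to-tip distances.  Computed with
#' \code{ape::vcv.phylo}.  Raw branch-length units by default; `scale_depth`
#' rescales to unit tree depth.
#'
#' @param tree a `phylo` with branch lengths.
#' @param scale_depth divide by the maximum root-to-tip distance.
#' @return symmetric matrix with tip labels on both dimensions.
#' @export
phylo_vcv <- function(tree, scale_depth = FALSE) {
  validate_tree(tree, allow_zero = TRUE)
  C <- ape::vcv.phylo(tree)
  if (scale_depth) C <- C / max(diag(C))
  C
}

#' Per-tip equal-splits speciation rates (lambda-DR)
#'
#' For tip i with root-to-tip edges indexed `j = 1` (pendant) to `N_i`
#' (root-adjacent), the equal-splits measure is
#' `ES_i = sum_j l_j * 2^-(j - 1)` — a weighted average of branch lengths
#' that emphasises the recent past — and the DR speciation-rate estimate is
#' `lambda_DR_i = 1 / ES_i`.
#'
#' Polytomies leave the edge index j ill-defined and are rejected unless
#' `resolve_polytomies = TRUE`, which resolves them randomly (seeded) with
#' zero-length internal edges.
#'
#' @param tree a `phylo` with strictly positive branch lengths.
#' @param resolve_polytomies randomly resolve polytomies before computing.
#' @param seed seed for the random resolution.
#' @return data frame: `species`, `es`, `lambda_dr`, and a `scope` attribute
#'   recording that rates were computed on the full tree.
#' @export
dr_statistic <- function(tree, resolve_polytomies = FALSE, seed = 1L) {
  validate_tree(tree, allow_zero = TRUE)
  if (!ape::is.binary(tree)) {
    if (!resolve_polytomies)
      stop("tree contains polytomies; set resolve_polytomies = TRUE ",
           "for a seeded random resolution with zero-length edges")
    set.seed(seed)
    tree <- ape::multi2di(tree, random = TRUE)
  }
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- ntip + 1L
  es <- numeric(ntip)
  for (i in seq_len(ntip)) {
    node <- i
    w <- 1
    acc <- 0
    while (node != root) {
      acc <- acc + elen[node] * w
      w <- w / 2
      node <- parent[node]
    }
    es[i] <- acc
  }
  if (any(es <= 0))
    stop("zero-length root-to-tip path; lambda-DR undefined for: ",
         paste(tree$tip.label[es <= 0], collapse = ", "))
  out <- data.frame(species = tree$tip.label, es = es, lambda_dr = 1 / es,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "scope") <- "full_tree"
  out
}

#' Subset full-tree rates to the species retained in an analysis
#'
#' Rates are computed once on the complete phylogeny and merely subset here
#' — never recomputed on a pruned tree, which would bias them downward by
#' discarding splits involving the removed species.
#'
#' @param rates output of [dr_statistic()].
#' @param keep character vector of species to retain.
#' @return the subset table, in the order of `keep`.
#' @export
restrict_rates <- function(rates, keep) {
  unknown <- setdiff(keep, rates$species)
  if (length(unknown))
    stop("species not in the rate table: ", paste(unknown, collapse = ", "))
  out <- rates[match(keep, rates$species), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scope") <- "full_tree_subset"
  out
}
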