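# Pairwise range-overlap matrices and distribution summaries.

#' Compute the species-by-species range overlap matrix
#'
#' `O[i, j]` is the area of intersection of the dissolved ranges of species
#' i and j; the diagonal holds each species' dissolved range area.  Pairs
#' whose bounding boxes are disjoint are skipped (their overlap is exactly
#' zero), which leaves the result identical to the exhaustive computation.
#'
#' @param ranges a projected or planar `range_set`.
#' @param prefilter skip bounding-box-disjoint pairs (default TRUE; FALSE
#'   forces the exhaustive double loop, useful for cross-checks).
#' @return symmetric numeric matrix with species names on both dimensions.
#' @export
compute_overlap_matrix <- function(ranges, prefilter = TRUE) {
  stopifnot(inherits(ranges, "range_set"))
  if (ranges$projection == "lonlat")
    stop("project ranges with project_equal_area() before measuring overlap")
  soups <- species_soups(ranges)
  sp <- names(soups)
  n <- length(sp)
  O <- matrix(0, n, n, dimnames = list(sp, sp))
  bboxes <- lapply(soups, soup_bbox)
  for (i in seq_len(n)) {
    O[i, i] <- soup_area(soups[[i]])
    if (i == n) break
    for (j in seq(i + 1L, n)) {
      if (prefilter && bbox_disjoint(bboxes[[i]], bboxes[[j]])) next
      a <- soup_area(soup_intersect(soups[[i]], soups[[j]]))
      O[i, j] <- O[j, i] <- max(a, 0)
    }
  }
  O
}

#' Range size table (diagonal of the overlap matrix)
#'
#' @param overlap an overlap matrix from [compute_overlap_matrix()].
#' @return data frame with `species` and `area`.
#' @export
range_size_table <- function(overlap) {
  data.frame(species = rownames(overlap), area = diag(overlap),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize range-size and overlap-size distributions
#'
#' Returns the means of the natural-log-transformed data and histogram bins
#' for (a) range sizes and (b) the strictly positive pairwise overlaps;
#' zero overlaps (allopatric pairs) are excluded from the log summary.
#'
#' @param range_sizes named numeric vector or `range_size_table()` output.
#' @param overlap overlap matrix; only the off-diagonal upper triangle is
#'   used.
#' @param bins suggested histogram bin count.
#' @return list with `range_log_mean`, `overlap_log_mean`, `range_hist`,
#'   `overlap_hist` (each a list of breaks/counts), `n_pairs_positive`, and
#'   `overlap_empty` (TRUE when no pair overlaps).
#' @export
summarize_distributions <- function(range_sizes, overlap, bins = 20) {
  if (is.data.frame(range_sizes)) {
    range_sizes <- stats::setNames(range_sizes$area, range_sizes$species)
  }
  if (!length(range_sizes)) stop("empty range-size input")
  pos_rs <- range_sizes[range_sizes > 0]
  ov <- overlap[upper.tri(overlap)]
  pos_ov <- ov[ov > 0]
  hist_of <- function(x) {
    h <- graphics::hist(x, breaks = bins, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  }
  list(
    range_log_mean = mean(log(pos_rs)),
    overlap_log_mean = if (length(pos_ov)) mean(log(pos_ov)) else NA_real_,
    range_hist = hist_of(log(pos_rs)),
    overlap_hist = if (length(pos_ov)) hist_of(log(pos_ov)) else NULL,
    n_pairs_positive = length(pos_ov),
    overlap_empty = length(pos_ov) == 0
  )
}
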