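# Exact planar polygon geometry on a signed convex decomposition.
#
# Every species range is reduced to a "soup": a list of convex pieces
# (matrices of vertices, counter-clockwise) each carrying a sign, such that
# the signed sum of piece indicator functions equals the indicator function
# of the range (outer rings +1, holes -1, inclusion-exclusion terms for
# overlapping features +/-1).  Because indicators multiply, the intersection
# of two soups is the soup of all pairwise convex clips with multiplied
# signs, and areas, unions and intersections all stay exact in floating
# point up to the usual rounding.

# ---- rings ------------------------------------------------------------------

#' Signed area of a polygon ring (shoelace formula)
#'
#' @param xy two-column matrix of vertices (open or closed ring).
#' @return Signed area: positive for counter-clockwise rings.
#' @keywords internal
ring_area <- function(xy) {
  xy <- ring_open(xy)
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# drop a repeated closing vertex and exact duplicates of consecutive vertices
ring_open <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) >= 2 && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  if (nrow(xy) >= 2) {
    keep <- c(TRUE, rowSums(abs(diff(xy))) > 0)
    xy <- xy[keep, , drop = FALSE]
  }
  xy
}

ring_ccw <- function(xy) {
  if (ring_area(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

ring_is_convex <- function(xy) {
  n <- nrow(xy)
  if (n < 4) return(TRUE)
  ip <- c(2:n, 1); inx <- c(3:n, 1, 2)
  cr <- (xy[ip, 1] - xy[, 1]) * (xy[inx, 2] - xy[ip, 2]) -
        (xy[ip, 2] - xy[, 2]) * (xy[inx, 1] - xy[ip, 1])
  all(cr >= -1e-12 * max(abs(cr), 1))
}

point_in_tri <- function(p, a, b, c) {
  d1 <- (p[1] - b[1]) * (a[2] - b[2]) - (a[1] - b[1]) * (p[2] - b[2])
  d2 <- (p[1] - c[1]) * (b[2] - c[2]) - (b[1] - c[1]) * (p[2] - c[2])
  d3 <- (p[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (p[2] - a[2])
  !(any(c(d1, d2, d3) < 0) && any(c(d1, d2, d3) > 0))
}

#' Triangulate a simple polygon ring
#'
#' Fan triangulation for convex rings, ear clipping otherwise.
#'
#' @param xy two-column vertex matrix of a simple (non self-intersecting) ring.
#' @return list of 3x2 triangle matrices, all counter-clockwise.
#' @keywords internal
triangulate_ring <- function(xy) {
  xy <- ring_ccw(ring_open(xy))
  n <- nrow(xy)
  if (n < 3) return(list())
  if (ring_is_convex(xy)) {
    return(lapply(2:(n - 1), function(i) xy[c(1, i, i + 1), , drop = FALSE]))
  }
  # ear clipping
  idx <- seq_len(n)
  tris <- vector("list", n - 2)
  k <- 0
  guard <- 0
  while (length(idx) > 3) {
    m <- length(idx)
    clipped <- FALSE
    for (t in seq_len(m)) {
      i0 <- idx[if (t == 1) m else t - 1]
      i1 <- idx[t]
      i2 <- idx[if (t == m) 1 else t + 1]
      a <- xy[i0, ]; b <- xy[i1, ]; cc <- xy[i2, ]
      cross <- (b[1] - a[1]) * (cc[2] - b[2]) - (b[2] - a[2]) * (cc[1] - b[1])
      if (cross <= 0) next   # reflex or degenerate vertex
      others <- setdiff(idx, c(i0, i1, i2))
      inside <- FALSE
      for (o in others) {
        if (point_in_tri(xy[o, ], a, b, cc)) { inside <- TRUE; break }
      }
      if (inside) next
      k <- k + 1
      tris[[k]] <- rbind(a, b, cc)
      idx <- idx[-t]
      clipped <- TRUE
      break
    }
    guard <- guard + 1
    if (!clipped || guard > 10 * n) {
      stop("ear clipping failed: ring is not simple; repair it first")
    }
  }
  k <- k + 1
  tris[[k]] <- xy[idx, , drop = FALSE]
  tris[seq_len(k)]
}

# proper intersection point of segments p1-p2 and p3-p4, or NULL
seg_intersection <- function(p1, p2, p3, p4) {
  r <- p2 - p1; s <- p4 - p3
  denom <- r[1] * s[2] - r[2] * s[1]
  if (abs(denom) < 1e-300) return(NULL)
  q <- p3 - p1
  t <- (q[1] * s[2] - q[2] * s[1]) / denom
  u <- (q[1] * r[2] - q[2] * r[1]) / denom
  eps <- 1e-12
  if (t <= eps || t >= 1 - eps || u <= eps || u >= 1 - eps) return(NULL)
  p1 + t * r
}

#' Repair a self-intersecting ring by splitting it at crossing points
#'
#' A figure-eight ("bow-tie") ring is split into its constituent simple
#' loops; each loop keeps its full coverage area.  Applied recursively, so
#' rings with several simple crossings are handled; coincident-edge
#' degeneracies are left untouched.
#'
#' @param xy two-column vertex matrix.
#' @return list of simple rings (two-column matrices).
#' @keywords internal
repair_ring <- function(xy) {
  xy <- ring_open(xy)
  n <- nrow(xy)
  if (n < 3) return(list())
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    js <- seq(i + 2, jmax)
    for (j in js) {
      p <- seg_intersection(xy[i, ], xy[i %% n + 1, ],
                            xy[j, ], xy[j %% n + 1, ])
      if (!is.null(p)) {
        loop1 <- rbind(p, xy[seq(i + 1, j), , drop = FALSE])
        rest <- if (j < n) seq(j + 1, n) else integer(0)
        loop2 <- rbind(p, xy[c(rest, seq_len(i)), , drop = FALSE])
        return(c(repair_ring(loop1), repair_ring(loop2)))
      }
    }
  }
  if (abs(ring_area(xy)) < 1e-300) list() else list(xy)
}

# ---- convex clipping --------------------------------------------------------

#' Clip a convex polygon by a convex polygon (Sutherland-Hodgman)
#'
#' @param subject,clip two-column CCW vertex matrices of convex polygons.
#' @return two-column matrix of the intersection (possibly with < 3 rows
#'   when the intersection is empty or degenerate).
#' @keywords internal
clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) < 3) return(out[0, , drop = FALSE])
    a <- clip[e, ]; b <- clip[if (e == nc) 1 else e + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    # signed distance of each subject vertex from the directed clip edge
    d <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    m <- nrow(out)
    nxt <- c(2:m, 1)
    new <- vector("list", 2L * m)
    k <- 0
    for (v in seq_len(m)) {
      w <- nxt[v]
      din <- d[v] >= 0
      dwn <- d[w] >= 0
      if (din) { k <- k + 1; new[[k]] <- out[v, ] }
      if (din != dwn) {
        t <- d[v] / (d[v] - d[w])
        k <- k + 1
        new[[k]] <- out[v, ] + t * (out[w, ] - out[v, ])
      }
    }
    out <- if (k == 0) subject[0, , drop = FALSE] else do.call(rbind, new[seq_len(k)])
  }
  out
}

# ---- soups ------------------------------------------------------------------

new_soup <- function(pieces = list(), signs = numeric(0)) {
  bb <- if (length(pieces)) {
    t(vapply(pieces, function(p) c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2])),
             numeric(4)))
  } else {
    matrix(numeric(0), 0, 4)
  }
  structure(list(pieces = pieces, signs = signs, bbox = bb), class = "geom_soup")
}

#' Build a signed convex soup from a polygon
#'
#' @param poly list with `outer` (ring matrix) and optional `holes`
#'   (list of ring matrices, assumed inside the outer ring).
#' @return a `geom_soup`.
#' @keywords internal
soup_from_polygon <- function(poly) {
  pieces <- triangulate_ring(poly$outer)
  signs <- rep(1, length(pieces))
  for (h in poly$holes %||% list()) {
    ht <- triangulate_ring(h)
    pieces <- c(pieces, ht)
    signs <- c(signs, rep(-1, length(ht)))
  }
  new_soup(pieces, signs)
}

soup_from_multipolygon <- function(mp) {
  soups <- lapply(mp, soup_from_polygon)
  new_soup(unlist(lapply(soups, `[[`, "pieces"), recursive = FALSE),
           unlist(lapply(soups, `[[`, "signs")))
}

soup_area <- function(soup) {
  if (!length(soup$pieces)) return(0)
  sum(soup$signs * vapply(soup$pieces, ring_area, numeric(1)))
}

soup_bbox <- function(soup) {
  if (!nrow(soup$bbox)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
  c(min(soup$bbox[, 1]), min(soup$bbox[, 2]), max(soup$bbox[, 3]), max(soup$bbox[, 4]))
}

bbox_disjoint <- function(a, b) {
  any(is.na(a)) || any(is.na(b)) ||
    a[3] < b[1] || b[3] < a[1] || a[4] < b[2] || b[4] < a[2]
}

#' Intersect two signed soups
#'
#' Pairwise convex clips with multiplied signs; piece pairs with disjoint
#' bounding boxes are skipped (the clip would be empty).
#'
#' @keywords internal
soup_intersect <- function(a, b) {
  na <- length(a$pieces); nb <- length(b$pieces)
  if (!na || !nb) return(new_soup())
  pieces <- vector("list", na * nb)
  signs <- numeric(na * nb)
  k <- 0
  for (i in seq_len(na)) {
    bi <- a$bbox[i, ]
    for (j in seq_len(nb)) {
      bj <- b$bbox[j, ]
      if (bi[3] < bj[1] || bj[3] < bi[1] || bi[4] < bj[2] || bj[4] < bi[2]) next
      cl <- clip_convex(a$pieces[[i]], b$pieces[[j]])
      if (nrow(cl) < 3) next
      ar <- ring_area(cl)
      sc <- max(bi[3] - bi[1], bi[4] - bi[2], bj[3] - bj[1], bj[4] - bj[2])
      if (abs(ar) <= 1e-14 * sc * sc) next
      k <- k + 1
      pieces[[k]] <- cl
      signs[k] <- a$signs[i] * b$signs[j]
    }
  }
  new_soup(pieces[seq_len(k)], signs[seq_len(k)])
}

#' Union of a list of soups by incremental inclusion-exclusion
#'
#' ind(U + A) = ind(U) + ind(A) - ind(U)*ind(A), so the union soup is the
#' concatenation of both soups plus the sign-negated intersection soup.
#'
#' @keywords internal
soup_union <- function(soups) {
  soups <- soups[vapply(soups, function(s) length(s$pieces) > 0, logical(1))]
  if (!length(soups)) return(new_soup())
  u <- soups[[1]]
  for (s in soups[-1]) {
    inter <- soup_intersect(u, s)
    u <- new_soup(c(u$pieces, s$pieces, inter$pieces),
                  c(u$signs, s$signs, -inter$signs))
  }
  u
}

#' Area of pairwise intersection of two soups
#' @keywords internal
soup_intersection_area <- function(a, b) {
  if (bbox_disjoint(soup_bbox(a), soup_bbox(b))) return(0)
  soup_area(soup_intersect(a, b))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
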