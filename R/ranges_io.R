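# Reading, filtering and writing species range polygons.
#
# A `range_set` holds one multipolygon per species (a list of polygons, each
# `list(outer = <ring matrix>, holes = <list of ring matrices>)`), the
# per-feature attribute table, and a projection tag: "lonlat" for geographic
# degrees, "cea" after equal-area projection (km), or "planar" for synthetic
# landscapes in abstract units.

#' Specify attribute-based feature filtering
#'
#' IUCN-style range files attach a presence and an origin code to every
#' feature; features whose codes indicate uncertain occurrence or
#' introduction are excluded before ranges are dissolved and measured.
#' The excluded code lists are configuration, not hard-coded.
#'
#' @param presence_field,origin_field names of the feature properties
#'   holding the presence and origin codes.
#' @param exclude_presence character vector of presence codes to drop.
#' @param exclude_origin character vector of origin codes to drop.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(presence_field = "presence",
                        origin_field = "origin",
                        exclude_presence = c("uncertain", "possibly_extinct"),
                        exclude_origin = "introduced") {
  structure(list(presence_field = presence_field,
                 origin_field = origin_field,
                 exclude_presence = exclude_presence,
                 exclude_origin = exclude_origin),
            class = "filter_spec")
}

new_range_set <- function(geoms, features, projection, report = NULL) {
  structure(list(species = names(geoms),
                 geoms = geoms,
                 features = features,
                 projection = projection,
                 report = report),
            class = "range_set")
}

#' @export
print.range_set <- function(x, ...) {
  cat(sprintf("range_set: %d species, projection '%s'\n",
              length(x$species), x$projection))
  if (!is.null(x$report)) {
    cat(sprintf("  features read %d, dropped %d, repaired %d\n",
                x$report$n_read, x$report$n_dropped, x$report$n_repaired))
    if (length(x$report$dropped_species)) {
      cat("  species lost to filtering:",
          paste(x$report$dropped_species, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

# convert one GeoJSON geometry node to a multipolygon (list of polygons)
geojson_to_multipolygon <- function(geom) {
  ring_mat <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(p) as.numeric(p[1:2])))
    ring_open(m)
  }
  poly_from_rings <- function(rings) {
    list(outer = ring_mat(rings[[1]]),
         holes = lapply(rings[-1], ring_mat))
  }
  switch(geom$type,
    Polygon = list(poly_from_rings(geom$coordinates)),
    MultiPolygon = lapply(geom$coordinates, poly_from_rings),
    stop("unsupported geometry type: ", geom$type)
  )
}

multipolygon_to_geojson <- function(mp) {
  close_ring <- function(xy) {
    xy <- ring_open(xy)
    unname(lapply(seq_len(nrow(xy) + 1L), function(i) {
      j <- if (i > nrow(xy)) 1L else i
      c(xy[j, 1], xy[j, 2])
    }))
  }
  list(type = "MultiPolygon",
       coordinates = lapply(mp, function(poly) {
         c(list(close_ring(poly$outer)), lapply(poly$holes, close_ring))
       }))
}

# repair every ring of a multipolygon; returns list(mp, n_repaired)
repair_multipolygon <- function(mp) {
  n_rep <- 0L
  out <- list()
  for (poly in mp) {
    fixed_outer <- repair_ring(poly$outer)
    if (length(fixed_outer) > 1L) n_rep <- n_rep + 1L
    fixed_holes <- list()
    for (h in poly$holes) {
      fh <- repair_ring(h)
      if (length(fh) > 1L) n_rep <- n_rep + 1L
      fixed_holes <- c(fixed_holes, fh)
    }
    if (length(fixed_outer) == 1L) {
      out <- c(out, list(list(outer = fixed_outer[[1]], holes = fixed_holes)))
    } else {
      # a split outer ring becomes several polygons; holes are re-attached to
      # the loop that contains their first vertex
      for (loop in fixed_outer) {
        hs <- Filter(function(h) {
          point_in_ring(h[1, ], loop)
        }, fixed_holes)
        out <- c(out, list(list(outer = loop, holes = hs)))
      }
    }
  }
  list(mp = out, n_repaired = n_rep)
}

# even-odd ray-casting point-in-ring test
point_in_ring <- function(p, xy) {
  xy <- ring_open(xy)
  n <- nrow(xy)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((xy[i, 2] > p[2]) != (xy[j, 2] > p[2])) {
      xint <- xy[i, 1] + (p[2] - xy[i, 2]) / (xy[j, 2] - xy[i, 2]) *
        (xy[j, 1] - xy[i, 1])
      if (p[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Load species ranges from GeoJSON with attribute filtering
#'
#' Reads a FeatureCollection with one feature per species sub-range
#' (properties: `species_id` plus presence and origin codes), drops features
#' failing the filter, repairs self-intersecting rings by splitting them at
#' crossing points, and collects the retained features per species.  The
#' per-species union (dissolve) is applied whenever areas or overlaps are
#' measured, so multiple seasonal or subspecies features never double-count.
#'
#' @param path GeoJSON file.
#' @param filters a [filter_spec()]; `NULL` disables filtering.
#' @param projection projection tag of the file coordinates: `"lonlat"`
#'   (geographic degrees, the default for real range files) or `"planar"`.
#' @return A `range_set`; its `report` lists features read, dropped and
#'   repaired and any species removed entirely by filtering.
#' @export
load_ranges <- function(path, filters = filter_spec(), projection = "lonlat") {
  if (!file.exists(path)) stop("range file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  feats <- gj$features
  n_read <- length(feats)
  if (!n_read) stop("no features in ", path)

  get_prop <- function(f, field) {
    v <- f$properties[[field]]
    if (is.null(v)) NA_character_ else as.character(v)
  }
  species <- vapply(feats, get_prop, character(1), field = "species_id")
  if (anyNA(species)) stop("features without a species_id property")

  presence <- origin <- rep(NA_character_, n_read)
  kept <- rep(TRUE, n_read)
  if (!is.null(filters)) {
    presence <- vapply(feats, get_prop, character(1), field = filters$presence_field)
    origin <- vapply(feats, get_prop, character(1), field = filters$origin_field)
    if ((length(filters$exclude_presence) && all(is.na(presence))) ||
        (length(filters$exclude_origin) && all(is.na(origin)))) {
      stop("filter requested on fields '", filters$presence_field, "'/'",
           filters$origin_field, "' but no feature carries them")
    }
    kept <- !(presence %in% filters$exclude_presence) &
            !(origin %in% filters$exclude_origin)
  }

  n_repaired <- 0L
  geoms <- list()
  for (i in which(kept)) {
    mp <- geojson_to_multipolygon(feats[[i]]$geometry)
    rep_res <- repair_multipolygon(mp)
    n_repaired <- n_repaired + rep_res$n_repaired
    sp <- species[i]
    geoms[[sp]] <- c(geoms[[sp]] %||% list(), rep_res$mp)
  }
  dropped_species <- setdiff(unique(species), names(geoms))
  report <- list(n_read = n_read,
                 n_dropped = sum(!kept),
                 n_repaired = n_repaired,
                 dropped_species = dropped_species)
  features <- data.frame(species = species, presence = presence,
                         origin = origin, kept = kept,
                         stringsAsFactors = FALSE)
  new_range_set(geoms, features, projection, report)
}

#' Write a range set as a GeoJSON FeatureCollection
#'
#' One feature per species; extra per-species properties can be attached
#' through `properties` (a named list of named vectors indexed by species).
#'
#' @param ranges a `range_set`.
#' @param path output file.
#' @param properties optional named list; each element is a vector named by
#'   species, written as an extra feature property.
#' @return `path`, invisibly.
#' @export
write_ranges_geojson <- function(ranges, path, properties = NULL) {
  feats <- lapply(ranges$species, function(sp) {
    props <- list(species_id = sp)
    ft <- ranges$features[ranges$features$species == sp & ranges$features$kept, , drop = FALSE]
    props$presence <- if (nrow(ft)) ft$presence[1] else "extant"
    props$origin <- if (nrow(ft)) ft$origin[1] else "native"
    for (nm in names(properties %||% list())) {
      v <- properties[[nm]][[sp]]
      if (!is.null(v) && !is.na(v)) props[[nm]] <- v
    }
    list(type = "Feature",
         properties = props,
         geometry = multipolygon_to_geojson(ranges$geoms[[sp]]))
  })
  for (ex in ranges$extra %||% list()) {
    feats <- c(feats, list(list(
      type = "Feature",
      properties = list(species_id = ex$species, presence = ex$presence,
                        origin = ex$origin),
      geometry = multipolygon_to_geojson(ex$mp))))
  }
  fc <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

# dissolved signed-soup per species (the measurement representation)
species_soups <- function(ranges) {
  soups <- lapply(ranges$geoms, function(mp) {
    soup_union(lapply(mp, soup_from_polygon))
  })
  names(soups) <- ranges$species
  soups
}

#' Dissolved range area per species
#'
#' @param ranges a `range_set` (projected or planar).
#' @return named numeric vector of areas (km^2 after [project_equal_area()],
#'   landscape units^2 for synthetic planar ranges).
#' @export
range_areas <- function(ranges) {
  vapply(species_soups(ranges), soup_area, numeric(1))
}
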