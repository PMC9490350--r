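# GeoJSON polygon handling: centroids and queen contiguity. Hand-rolled on
# jsonlite output because no simple-features package is assumed; adequate
# for polygonal lattices (shared edges / corner touches), not for arbitrary
# curved boundaries.

#' Read polygons from a GeoJSON FeatureCollection
#'
#' Each feature must carry an `area_id` property and a Polygon or
#' MultiPolygon geometry. Returns the outer-ring vertex lists plus
#' area-weighted (shoelace) centroids.
#'
#' @param path GeoJSON file path.
#' @return list with `area_ids`, `centroids` (n x 2) and `rings` (list of
#'   vertex matrices per area).
#' @export
read_geojson_polygons <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(g$features)) stop("GeoJSON must be a FeatureCollection")
  area_ids <- character(0)
  rings <- list()
  cents <- NULL
  for (ft in g$features) {
    id <- ft$properties$area_id
    if (is.null(id)) stop("every feature needs an 'area_id' property")
    geom <- ft$geometry
    polys <- switch(geom$type,
                    Polygon = list(geom$coordinates),
                    MultiPolygon = geom$coordinates,
                    stop("unsupported geometry type: ", geom$type))
    rr <- list()
    a_tot <- 0; cx <- 0; cy <- 0
    for (poly in polys) {
      ring <- do.call(rbind, lapply(poly[[1L]], function(p) c(p[[1L]], p[[2L]])))
      rr[[length(rr) + 1L]] <- ring
      sc <- shoelace_centroid(ring)
      a_tot <- a_tot + sc$area
      cx <- cx + sc$area * sc$cx
      cy <- cy + sc$area * sc$cy
    }
    area_ids <- c(area_ids, as.character(id))
    rings[[length(rings) + 1L]] <- rr
    cents <- rbind(cents, c(cx / a_tot, cy / a_tot))
  }
  list(area_ids = area_ids, centroids = cents, rings = rings)
}

shoelace_centroid <- function(ring) {
  # ring: closed or open vertex matrix; returns unsigned area + centroid
  if (!isTRUE(all.equal(ring[1L, ], ring[nrow(ring), ])))
    ring <- rbind(ring, ring[1L, ])
  x <- ring[, 1L]; y <- ring[, 2L]
  k <- seq_len(nrow(ring) - 1L)
  cross <- x[k] * y[k + 1L] - x[k + 1L] * y[k]
  a <- sum(cross) / 2
  list(area = abs(a),
       cx = sum((x[k] + x[k + 1L]) * cross) / (6 * a),
       cy = sum((y[k] + y[k + 1L]) * cross) / (6 * a))
}

point_on_segment <- function(p, a, b, tol) {
  # is point p on segment ab (within tol)?
  ab <- b - a
  ap <- p - a
  L2 <- sum(ab^2)
  if (L2 == 0) return(sqrt(sum(ap^2)) <= tol)
  t <- sum(ap * ab) / L2
  if (t < -tol || t > 1 + tol) return(FALSE)
  proj <- a + pmin(pmax(t, 0), 1) * ab
  sqrt(sum((p - proj)^2)) <= tol
}

rings_touch <- function(rings_i, rings_j, tol) {
  # queen contiguity: the polygons share at least one boundary point.
  # Sufficient test for lattices: some vertex of one lies on the boundary
  # of the other (covers shared edges, T-junctions and corner touches).
  for (ri in rings_i) for (rj in rings_j) {
    nj <- nrow(rj)
    for (v in seq_len(nrow(ri))) {
      p <- ri[v, ]
      for (s in seq_len(nj - 1L)) {
        if (point_on_segment(p, rj[s, ], rj[s + 1L, ], tol)) return(TRUE)
      }
      if (point_on_segment(p, rj[nj, ], rj[1L, ], tol)) return(TRUE)
    }
    ni <- nrow(ri)
    for (v in seq_len(nrow(rj))) {
      p <- rj[v, ]
      for (s in seq_len(ni - 1L)) {
        if (point_on_segment(p, ri[s, ], ri[s + 1L, ], tol)) return(TRUE)
      }
      if (point_on_segment(p, ri[ni, ], ri[1L, ], tol)) return(TRUE)
    }
  }
  FALSE
}

#' Queen-contiguity adjacency from polygons
#'
#' Two areas are neighbours iff their boundaries share at least one point
#' (an edge or just a corner). Input is either a GeoJSON path or the list
#' returned by [read_geojson_polygons()]. Areas without any neighbour
#' trigger a warning (islands get independent effects in the CAR models).
#'
#' @param polygons GeoJSON path or parsed polygon list.
#' @param tol geometric tolerance, relative to the bounding-box diagonal.
#' @return binary symmetric n x n matrix, zero diagonal.
#' @export
build_adjacency <- function(polygons, tol = 1e-9) {
  if (is.character(polygons)) polygons <- read_geojson_polygons(polygons)
  rings <- polygons$rings
  n <- length(rings)
  allv <- do.call(rbind, unlist(rings, recursive = FALSE))
  scale <- sqrt(sum((apply(allv, 2L, max) - apply(allv, 2L, min))^2))
  tol_abs <- max(tol * max(scale, 1), 1e-12)
  W <- matrix(0, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (rings_touch(rings[[i]], rings[[j]], tol_abs)) W[i, j] <- W[j, i] <- 1
    }
  }
  isl <- which(rowSums(W) == 0)
  if (length(isl))
    warning(sprintf("%d area(s) have no neighbours: %s", length(isl),
                    paste(polygons$area_ids[isl], collapse = ", ")))
  W
}
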