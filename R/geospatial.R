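## Great-circle geometry and convex-hull range sizes. All distances are
## measured on a sphere of authalic radius 6371.0088 km, adequate over the
## sub-continental spans this package targets.

EARTH_RADIUS_M <- 6371008.8

check_lonlat <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite coordinates")
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]")
  invisible(TRUE)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Given two
#' points it returns a scalar; given a two-column \code{cbind(lon, lat)}
#' matrix it returns the full symmetric distance matrix.
#'
#' @param p1 either \code{c(lon, lat)} or an n x 2 matrix of
#'   \code{(lon, lat)} rows.
#' @param p2 \code{c(lon, lat)} or an n x 2 matrix; omit to get all
#'   pairwise distances among the rows of \code{p1}.
#' @return Distance(s) in km.
#' @export
great_circle_km <- function(p1, p2 = NULL) {
  p1 <- rbind(p1)
  check_lonlat(p1[, 1L], p1[, 2L])
  if (is.null(p2)) {
    n <- nrow(p1)
    d <- matrix(0, n, n)
    if (n > 1L) {
      idx <- which(upper.tri(d), arr.ind = TRUE)
      v <- geosphere::distHaversine(p1[idx[, 1L], , drop = FALSE],
                                    p1[idx[, 2L], , drop = FALSE],
                                    r = EARTH_RADIUS_M) / 1000
      d[idx] <- v
      d <- d + t(d)
    }
    dimnames(d) <- list(rownames(p1), rownames(p1))
    return(d)
  }
  p2 <- rbind(p2)
  check_lonlat(p2[, 1L], p2[, 2L])
  drop(geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M) / 1000)
}

#' Convex-hull range size in square kilometres
#'
#' Deduplicates the occurrence records, takes the planar convex hull in
#' unprojected lon/lat, and measures the hull polygon on the sphere
#' (radius 6371.0088 km). Taxa with fewer than three unique, non-collinear
#' records have no measurable hull and return \code{NA} with a reason
#' attribute. Ranges spanning the antimeridian are rejected: the intended
#' study domain is far from it and naive lon/lat hulls would be wrong
#' there.
#'
#' @param points n x 2 matrix or data.frame of \code{(lon, lat)} records.
#' @return Hull area in km^2, or \code{NA} (attribute \code{"reason"}
#'   explains why).
#' @export
convex_hull_area_km2 <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  check_lonlat(pts[, 1L], pts[, 2L])
  if (diff(range(pts[, 1L])) > 180)
    stop("occurrence records span the antimeridian; outside supported domain")
  pts <- unique(pts)
  if (nrow(pts) < 3L)
    return(structure(NA_real_, reason = "fewer than 3 unique records"))
  hull <- grDevices::chull(pts)
  if (length(hull) < 3L)
    return(structure(NA_real_, reason = "collinear records"))
  poly <- pts[hull, , drop = FALSE]
  abs(geosphere::areaPolygon(poly, a = EARTH_RADIUS_M, f = 0)) / 1e6
}

#' Range-size table from occurrence records
#'
#' @param occurrences data.frame with columns \code{taxon}, \code{lon},
#'   \code{lat} (see [read_occurrences()]).
#' @return A data.frame with one row per taxon: \code{taxon},
#'   \code{n_records}, \code{hull_area_km2} (\code{NA} when the hull is
#'   not measurable).
#' @export
range_size_table <- function(occurrences) {
  taxa <- unique(occurrences$taxon)
  rows <- lapply(taxa, function(tx) {
    sub <- occurrences[occurrences$taxon == tx, c("lon", "lat")]
    data.frame(taxon = tx, n_records = nrow(sub),
               hull_area_km2 = as.numeric(convex_hull_area_km2(sub)))
  })
  do.call(rbind, rows)
}

#' Mean species range size per location
#'
#' Unweighted mean convex-hull area over the taxa recorded at each
#' location's quadrats; taxa without a measurable hull are excluded.
#'
#' @param cm a \code{community_matrix}.
#' @param st a \code{site_table} covering the same quadrats.
#' @param ranges a range-size table from [range_size_table()].
#' @return Data.frame: \code{location_id}, \code{n_taxa} (scorable taxa),
#'   \code{mean_range_km2} (\code{NA} when no taxon is scorable).
#' @export
mean_range_size_per_location <- function(cm, st, ranges) {
  check_alignment(cm, st)
  cm <- cm[st$quadrat_id, , drop = FALSE]
  area <- stats::setNames(ranges$hull_area_km2, ranges$taxon)
  locs <- sort(unique(st$location_id))
  rows <- lapply(locs, function(l) {
    sub <- cm[st$location_id == l, , drop = FALSE]
    taxa <- colnames(sub)[colSums(sub) > 0L]
    a <- area[intersect(taxa, names(area))]
    a <- a[!is.na(a)]
    data.frame(location_id = l, n_taxa = length(a),
               mean_range_km2 = if (length(a)) mean(a) else NA_real_)
  })
  do.call(rbind, rows)
}
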