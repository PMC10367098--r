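## Planar geometry: polygons, point-in-polygon, boundary distance, projection.
## Polygons are two-column matrices (x, y) in km; the closing vertex may be
## present or absent, both are accepted.

#' Normalise a polygon to an open ring matrix
#'
#' @param polygon two-column matrix or data frame of vertices (km); a
#'   repeated closing vertex is dropped.
#' @return matrix with columns \code{x}, \code{y}
#' @keywords internal
as_ring <- function(polygon) {
  p <- as.matrix(polygon)
  if (ncol(p) < 2L) stop("polygon must have two coordinate columns")
  p <- p[, 1:2, drop = FALSE]
  storage.mode(p) <- "double"
  if (nrow(p) >= 2L && all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) < 3L) stop("polygon is degenerate: fewer than 3 distinct vertices")
  colnames(p) <- c("x", "y")
  p
}

#' Axis-aligned square study-area polygon
#'
#' Convenience constructor for the ~50 km x 50 km district extents the
#' synthetic survey emulates.
#'
#' @param size_km side length in km
#' @param origin lower-left corner, length-2 numeric (km)
#' @return polygon vertex matrix
#' @export
square_polygon <- function(size_km = 50, origin = c(0, 0)) {
  as_ring(cbind(
    x = origin[1] + c(0, size_km, size_km, 0),
    y = origin[2] + c(0, 0, size_km, size_km)
  ))
}

#' Point-in-polygon test (even-odd rule)
#'
#' Crossing-number (even-odd) containment; points lying on the boundary
#' (within \code{tol}) count as inside. Handles non-convex polygons.
#'
#' @param x,y numeric vectors of point coordinates (km)
#' @param polygon polygon vertex matrix
#' @param tol boundary snap tolerance (km)
#' @return logical vector
#' @export
point_in_polygon <- function(x, y, polygon, tol = 1e-9) {
  p <- as_ring(polygon)
  n <- nrow(p)
  px <- p[, 1L]; py <- p[, 2L]
  qx <- c(px[-1L], px[1L]); qy <- c(py[-1L], py[1L])
  inside <- logical(length(x))
  for (k in seq_len(n)) {
    x1 <- px[k]; y1 <- py[k]; x2 <- qx[k]; y2 <- qy[k]
    crosses <- ((y1 > y) != (y2 > y))
    if (any(crosses)) {
      xc <- x1 + (y[crosses] - y1) / (y2 - y1) * (x2 - x1)
      idx <- which(crosses)[xc > x[crosses]]
      inside[idx] <- !inside[idx]
    }
  }
  on_edge <- dist_to_boundary(x, y, p) <= tol
  inside | on_edge
}

#' Distance from points to a polygon boundary
#'
#' Minimum Euclidean distance to any edge segment.
#'
#' @inheritParams point_in_polygon
#' @return numeric vector of distances (km)
#' @export
dist_to_boundary <- function(x, y, polygon) {
  p <- as_ring(polygon)
  n <- nrow(p)
  px <- p[, 1L]; py <- p[, 2L]
  qx <- c(px[-1L], px[1L]); qy <- c(py[-1L], py[1L])
  d2 <- rep(Inf, length(x))
  for (k in seq_len(n)) {
    vx <- qx[k] - px[k]; vy <- qy[k] - py[k]
    len2 <- vx * vx + vy * vy
    if (len2 == 0) {
      t <- 0
    } else {
      t <- pmin(1, pmax(0, ((x - px[k]) * vx + (y - py[k]) * vy) / len2))
    }
    dx <- x - (px[k] + t * vx)
    dy <- y - (py[k] + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

#' Polygon bounding box
#' @param polygon polygon vertex matrix
#' @return named numeric: xmin, xmax, ymin, ymax
#' @keywords internal
polygon_bbox <- function(polygon) {
  p <- as_ring(polygon)
  c(xmin = min(p[, 1L]), xmax = max(p[, 1L]),
    ymin = min(p[, 2L]), ymax = max(p[, 2L]))
}

#' Polygon area by the shoelace formula
#' @param polygon polygon vertex matrix
#' @return area (km^2), non-negative
#' @keywords internal
polygon_area <- function(polygon) {
  p <- as_ring(polygon)
  xs <- p[, 1L]; ys <- p[, 2L]
  xs2 <- c(xs[-1L], xs[1L]); ys2 <- c(ys[-1L], ys[1L])
  abs(sum(xs * ys2 - xs2 * ys)) / 2
}

## ---- projection -----------------------------------------------------------

EARTH_RADIUS_KM <- 6371.0088

#' Project geographic coordinates to planar km
#'
#' Spherical transverse Mercator centred on (\code{lon0}, \code{lat0}),
#' returning kilometre offsets. At district scale (tens of km) the
#' spherical-vs-ellipsoidal discrepancy is far below the GPS error of the
#' source data; the projection has an exact closed-form inverse
#' (\code{\link{unproject_lonlat}}), so coordinate round-trips are lossless.
#'
#' @param lon,lat numeric vectors, degrees
#' @param lon0,lat0 projection centre, degrees (defaults: centroid of input)
#' @return data frame with columns \code{x}, \code{y} (km) and attributes
#'   \code{lon0}, \code{lat0}
#' @export
project_lonlat <- function(lon, lat, lon0 = NULL, lat0 = NULL) {
  if (is.null(lon0)) lon0 <- mean(lon, na.rm = TRUE)
  if (is.null(lat0)) lat0 <- mean(lat, na.rm = TRUE)
  rad <- pi / 180
  dl <- (lon - lon0) * rad
  phi <- lat * rad
  B <- cos(phi) * sin(dl)
  x <- EARTH_RADIUS_KM * atanh(B)
  y <- EARTH_RADIUS_KM * (atan2(tan(phi), cos(dl)) - lat0 * rad)
  out <- data.frame(x = x, y = y)
  attr(out, "lon0") <- lon0
  attr(out, "lat0") <- lat0
  out
}

#' Invert the transverse Mercator projection
#'
#' @param x,y planar km as produced by \code{\link{project_lonlat}}
#' @param lon0,lat0 projection centre used on the way in, degrees
#' @return data frame with columns \code{lon}, \code{lat} (degrees)
#' @export
unproject_lonlat <- function(x, y, lon0, lat0) {
  rad <- pi / 180
  xr <- x / EARTH_RADIUS_KM
  D <- y / EARTH_RADIUS_KM + lat0 * rad
  lat <- asin(sin(D) / cosh(xr)) / rad
  lon <- lon0 + atan2(sinh(xr), cos(D)) / rad
  data.frame(lon = lon, lat = lat)
}

#' Read a boundary polygon from GeoJSON
#'
#' Accepts a FeatureCollection, Feature or bare Polygon/MultiPolygon geometry;
#' the outer ring of the first polygon is used. Geographic coordinates
#' (recognised by range, or forced via \code{geographic}) are projected to
#' planar km by \code{\link{project_lonlat}} centred on the ring centroid;
#' planar inputs are taken as km as-is.
#'
#' @param path GeoJSON file
#' @param geographic \code{NULL} to auto-detect, else logical
#' @return polygon vertex matrix (km); when projected, attributes \code{lon0}
#'   and \code{lat0} record the projection centre
#' @export
read_polygon <- function(path, geographic = NULL) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  geom <- gj
  if (identical(gj$type, "FeatureCollection")) geom <- gj$features[[1L]]$geometry
  if (identical(geom$type, "Feature")) geom <- geom$geometry
  ring <- switch(geom$type,
    Polygon = geom$coordinates[[1L]],
    MultiPolygon = geom$coordinates[[1L]][[1L]],
    stop("unsupported GeoJSON geometry type: ", geom$type)
  )
  m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1L]], pt[[2L]])))
  if (is.null(geographic)) {
    # lon/lat if within geographic bounds and spanning < 2 degrees (a district
    # is a fraction of a degree; planar-km rings span tens of units). Pass
    # `geographic` explicitly for ambiguous small planar polygons.
    in_bounds <- all(abs(m[, 1L]) <= 180) && all(abs(m[, 2L]) <= 90)
    small_span <- diff(range(m[, 1L])) < 2 && diff(range(m[, 2L])) < 2
    geographic <- in_bounds && small_span
  }
  if (geographic) {
    ctr_lon <- mean(m[, 1L]); ctr_lat <- mean(m[, 2L])
    xy <- project_lonlat(m[, 1L], m[, 2L], lon0 = ctr_lon, lat0 = ctr_lat)
    out <- as_ring(cbind(xy$x, xy$y))
    attr(out, "lon0") <- ctr_lon
    attr(out, "lat0") <- ctr_lat
    out
  } else {
    as_ring(m)
  }
}
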