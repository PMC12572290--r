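# Geometry container and geodesic helpers.
#
# Geometries are stored in WGS84 lon/lat. Metric work (buffering,
# circularity, overlap ratios, zonal statistics) happens in a per-feature
# local azimuthal-equidistant frame built from geodesic distance and azimuth
# about an origin, so results are correct at any latitude without UTM-zone
# bookkeeping.

#' Construct a point geometry
#'
#' @param lon,lat coordinates in decimal degrees (WGS84).
#' @return An object of class `ldis_geom`.
#' @export
geo_point <- function(lon, lat) {
  check_lonlat(lon, lat)
  structure(list(type = "point", xy = c(lon, lat)), class = "ldis_geom")
}

#' Construct a polygon geometry from a ring
#'
#' @param xy two-column matrix of lon/lat vertices (open or closed ring).
#' @return An object of class `ldis_geom`.
#' @export
geo_polygon <- function(xy) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, nrow(xy) >= 3)
  if (nrow(xy) > 3 && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  check_lonlat(xy[, 1], xy[, 2])
  structure(list(type = "polygon", xy = unname(xy)), class = "ldis_geom")
}

#' Construct a multipolygon geometry from a list of rings
#' @param rings list of two-column lon/lat matrices, one outer ring each.
#' @return An object of class `ldis_geom`.
#' @export
geo_multipolygon <- function(rings) {
  rings <- lapply(rings, function(r) geo_polygon(r)$xy)
  structure(list(type = "multipolygon", xy = rings), class = "ldis_geom")
}

#' Construct an annulus (ring-with-hole) geometry
#' @param outer,hole two-column lon/lat matrices; `hole` must lie inside `outer`.
#' @return An object of class `ldis_geom`.
#' @export
geo_annulus <- function(outer, hole) {
  structure(list(type = "annulus",
                 xy = list(outer = geo_polygon(outer)$xy, hole = geo_polygon(hole)$xy)),
            class = "ldis_geom")
}

#' Construct a linestring geometry (road segments)
#' @param xy two-column matrix of lon/lat vertices.
#' @return An object of class `ldis_geom`.
#' @export
geo_linestring <- function(xy) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, nrow(xy) >= 2)
  check_lonlat(xy[, 1], xy[, 2])
  structure(list(type = "linestring", xy = unname(xy)), class = "ldis_geom")
}

check_lonlat <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)) ||
      any(abs(lon) > 180) || any(abs(lat) > 90)) {
    stop("coordinates outside valid lon/lat ranges", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
format.ldis_geom <- function(x, ...) {
  switch(x$type,
    point = sprintf("<point %.5f %.5f>", x$xy[1], x$xy[2]),
    linestring = sprintf("<linestring, %d vertices>", nrow(x$xy)),
    polygon = sprintf("<polygon, %d vertices>", nrow(x$xy)),
    multipolygon = sprintf("<multipolygon, %d parts>", length(x$xy)),
    annulus = sprintf("<annulus, %d/%d vertices>", nrow(x$xy$outer), nrow(x$xy$hole)))
}

#' @export
print.ldis_geom <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

geom_type <- function(g) g$type

#' Representative lon/lat for a geometry (frame origin choice)
#' @keywords internal
geom_anchor <- function(g) {
  switch(g$type,
    point = g$xy,
    polygon = colMeans(g$xy),
    multipolygon = colMeans(do.call(rbind, g$xy)),
    annulus = colMeans(g$xy$outer))
}

#' Project lon/lat vertices into a local azimuthal-equidistant metric frame
#'
#' @param lonlat two-column matrix in degrees; `origin` length-2 lon/lat.
#' @return two-column matrix in metres (x east, y north of origin).
#' @keywords internal
local_xy <- function(lonlat, origin) {
  lonlat <- matrix(lonlat, ncol = 2)
  d <- geosphere::distGeo(origin, lonlat)
  b <- geosphere::bearing(matrix(origin, ncol = 2), lonlat)
  b[!is.finite(b)] <- 0
  br <- b * pi / 180
  cbind(d * sin(br), d * cos(br))
}

#' Inverse of [local_xy()]: metric frame back to lon/lat
#' @keywords internal
lonlat_xy <- function(xy, origin) {
  xy <- matrix(xy, ncol = 2)
  d <- sqrt(rowSums(xy^2))
  b <- atan2(xy[, 1], xy[, 2]) * 180 / pi
  out <- geosphere::destPoint(matrix(origin, ncol = 2), b, d)
  out[d == 0, 1] <- origin[1]
  out[d == 0, 2] <- origin[2]
  unname(out[, 1:2, drop = FALSE])
}

#' Geodesic area of a geometry in km^2 (WGS84 ellipsoid)
#'
#' @param g an `ldis_geom`.
#' @return Area in square kilometres (0 for points; outer minus hole for annuli).
#' @export
geo_area_km2 <- function(g) {
  area1 <- function(ring) abs(geosphere::areaPolygon(ring)) / 1e6
  switch(g$type,
    point = 0,
    polygon = area1(g$xy),
    multipolygon = sum(vapply(g$xy, area1, numeric(1))),
    annulus = area1(g$xy$outer) - area1(g$xy$hole))
}

#' Geometry ring in a local metric frame
#'
#' Returns the (outer) ring of `g` projected about `origin` (defaults to the
#' geometry's own anchor point).
#' @keywords internal
geom_local_ring <- function(g, origin = geom_anchor(g)) {
  switch(g$type,
    polygon = local_xy(g$xy, origin),
    annulus = local_xy(g$xy$outer, origin),
    point = matrix(rep(c(0, 0), 3), ncol = 2),
    stop("no single ring for type ", g$type, call. = FALSE))
}

# ---- WKT ------------------------------------------------------------------

#' Serialize a geometry to WKT
#' @param g an `ldis_geom`.
#' @return A WKT character scalar.
#' @export
geo_wkt <- function(g) {
  ring_txt <- function(xy) {
    xy <- rbind(xy, xy[1, ])
    paste(apply(xy, 1, function(p) sprintf("%.12g %.12g", p[1], p[2])), collapse = ", ")
  }
  switch(g$type,
    point = sprintf("POINT (%.12g %.12g)", g$xy[1], g$xy[2]),
    polygon = sprintf("POLYGON ((%s))", ring_txt(g$xy)),
    annulus = sprintf("POLYGON ((%s), (%s))", ring_txt(g$xy$outer), ring_txt(g$xy$hole)),
    multipolygon = sprintf("MULTIPOLYGON (%s)",
      paste(vapply(g$xy, function(r) sprintf("((%s))", ring_txt(r)), character(1)),
            collapse = ", ")))
}

#' Parse WKT (POINT, POLYGON, MULTIPOLYGON) into a geometry
#'
#' Only outer rings are retained; interior rings (holes) are dropped with a
#' warning.
#' @param s WKT character scalar.
#' @return An `ldis_geom`, or `NULL` for empty/unparseable input.
#' @export
geo_parse_wkt <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(NULL)
  s <- trimws(s)
  up <- toupper(s)
  num_ring <- function(txt) {
    pairs <- strsplit(trimws(strsplit(txt, ",")[[1]]), "\\s+")
    m <- do.call(rbind, lapply(pairs, function(p) as.numeric(p[1:2])))
    m
  }
  if (startsWith(up, "POINT")) {
    v <- as.numeric(strsplit(trimws(gsub(".*\\(|\\).*", "", s)), "\\s+")[[1]])
    return(geo_point(v[1], v[2]))
  }
  if (startsWith(up, "POLYGON")) {
    body <- sub("^[^(]*\\(", "", s); body <- sub("\\)\\s*$", "", body)
    rings <- regmatches(body, gregexpr("\\(([^()]*)\\)", body))[[1]]
    rings <- gsub("^\\(|\\)$", "", rings)
    if (length(rings) > 1) warning("interior rings dropped from POLYGON", call. = FALSE)
    return(geo_polygon(num_ring(rings[1])))
  }
  if (startsWith(up, "MULTIPOLYGON")) {
    inner <- regmatches(s, gregexpr("\\(\\(([^()]*)\\)", s))[[1]]
    inner <- gsub("^\\(\\(|\\)$", "", inner)
    return(geo_multipolygon(lapply(inner, num_ring)))
  }
  stop("unsupported WKT type in: ", substr(s, 1, 30), call. = FALSE)
}

# ---- GeoJSON --------------------------------------------------------------

geojson_to_geom <- function(gj) {
  if (is.null(gj) || is.null(gj$type)) return(NULL)
  type <- tolower(gj$type)
  cm <- function(cc) do.call(rbind, lapply(cc, function(p) as.numeric(unlist(p))))
  if (type == "point") {
    v <- as.numeric(unlist(gj$coordinates))
    return(geo_point(v[1], v[2]))
  }
  if (type == "linestring") return(geo_linestring(cm(gj$coordinates)))
  if (type == "polygon") return(geo_polygon(cm(gj$coordinates[[1]])))
  if (type == "multipolygon") {
    return(geo_multipolygon(lapply(gj$coordinates, function(poly) cm(poly[[1]]))))
  }
  stop("unsupported GeoJSON geometry type: ", gj$type, call. = FALSE)
}

geom_to_geojson <- function(g) {
  ring_list <- function(xy) {
    xy <- rbind(xy, xy[1, ])
    lapply(seq_len(nrow(xy)), function(i) c(xy[i, 1], xy[i, 2]))
  }
  switch(g$type,
    point = list(type = "Point", coordinates = c(g$xy[1], g$xy[2])),
    linestring = list(type = "LineString",
                      coordinates = lapply(seq_len(nrow(g$xy)),
                                           function(i) c(g$xy[i, 1], g$xy[i, 2]))),
    polygon = list(type = "Polygon", coordinates = list(ring_list(g$xy))),
    annulus = list(type = "Polygon",
                   coordinates = list(ring_list(g$xy$outer), ring_list(g$xy$hole))),
    multipolygon = list(type = "MultiPolygon",
                        coordinates = lapply(g$xy, function(r) list(ring_list(r)))))
}
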