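# Minimal in-memory raster container with plain-text (ESRI ASCII grid) IO.
#
# A raster lives in a local metric frame anchored at a WGS84 origin
# (lon/lat); cell coordinates are metres east/north of that origin. Site
# polygons are projected into the same frame for overlay work, and cells
# contribute their exact intersection area with the polygon (computed by
# half-plane clipping), not centre-point membership, so small sites do not
# hit quantization artifacts.

#' Construct a raster
#'
#' @param values numeric matrix; row 1 is the northernmost row.
#' @param xmin,ymin lower-left corner in metres of the local frame.
#' @param res cell size in metres.
#' @param origin length-2 lon/lat anchoring the local frame on the globe.
#' @param ... extra metadata stored as attributes (e.g. `year_min`,
#'   `year_max` for loss-year rasters).
#' @return An object of class `ldis_raster`.
#' @export
ldis_raster <- function(values, xmin, ymin, res, origin, ...) {
  stopifnot(is.matrix(values), res > 0, length(origin) == 2)
  structure(list(values = values, xmin = xmin, ymin = ymin, res = res,
                 origin = as.numeric(origin), meta = list(...)),
            class = "ldis_raster")
}

#' @export
print.ldis_raster <- function(x, ...) {
  cat(sprintf("<raster %d x %d, res %g m, origin %.4f %.4f>\n",
              nrow(x$values), ncol(x$values), x$res, x$origin[1], x$origin[2]))
  invisible(x)
}

raster_xmax <- function(r) r$xmin + ncol(r$values) * r$res
raster_ymax <- function(r) r$ymin + nrow(r$values) * r$res

#' Write / read a raster as an ESRI ASCII grid with a JSON sidecar
#'
#' The `.asc` file carries the grid; `<path>.json` carries the lon/lat
#' origin and any extra metadata. Text-only, self-contained.
#' @param r an `ldis_raster`; `path` output path ending in `.asc`.
#' @return `path` (write) or an `ldis_raster` (read).
#' @export
write_raster_asc <- function(r, path) {
  hdr <- c(sprintf("ncols %d", ncol(r$values)),
           sprintf("nrows %d", nrow(r$values)),
           sprintf("xllcorner %.6f", r$xmin),
           sprintf("yllcorner %.6f", r$ymin),
           sprintf("cellsize %.6f", r$res),
           "NODATA_value -9999")
  vals <- r$values
  vals[is.na(vals)] <- -9999
  body <- apply(vals, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  jsonlite::write_json(c(list(origin = r$origin), r$meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raster_asc
#' @export
read_raster_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  hv <- stats::setNames(vapply(hdr, function(h) as.numeric(h[2]), numeric(1)),
                        vapply(hdr, `[[`, character(1), 1))
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  vals[vals == hv[["nodata_value"]]] <- NA
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta <- side[setdiff(names(side), "origin")]
  do.call(ldis_raster, c(list(values = vals, xmin = hv[["xllcorner"]],
                              ymin = hv[["yllcorner"]], res = hv[["cellsize"]],
                              origin = as.numeric(side$origin)), meta))
}

# Project a geometry's (outer) ring into a raster's local frame.
ring_in_raster_frame <- function(geom, raster) {
  local_xy(if (geom$type == "annulus") geom$xy$outer else geom$xy, raster$origin)
}

#' Exact cell-coverage weights of a polygon over a raster
#'
#' Returns, for every raster cell whose rectangle intersects the ring, the
#' fraction of the cell covered by the ring (area-weighted; exact up to the
#' clipping arithmetic). Annuli yield outer-ring weights minus hole weights.
#'
#' @param geom an `ldis_geom` polygon or annulus.
#' @param raster an `ldis_raster`.
#' @return A tibble: `row`, `col`, `w` (in (0, 1]); plus attribute
#'   `covered_frac`, the share of the ring's area that lies on the raster.
#' @export
cell_weights <- function(geom, raster) {
  if (geom$type == "annulus") {
    wo <- ring_weights(local_xy(geom$xy$outer, raster$origin), raster)
    wh <- ring_weights(local_xy(geom$xy$hole, raster$origin), raster)
    w <- dplyr::full_join(wo, wh, by = c("row", "col"), suffix = c("", "_h")) |>
      dplyr::mutate(w = pmax(ifelse(is.na(.data$w), 0, .data$w) -
                               ifelse(is.na(.data$w_h), 0, .data$w_h), 0)) |>
      dplyr::filter(.data$w > 1e-12) |>
      dplyr::select("row", "col", "w")
    area_ring <- ring_area(local_xy(geom$xy$outer, raster$origin)) -
      ring_area(local_xy(geom$xy$hole, raster$origin))
    attr(w, "covered_frac") <- min(sum(w$w) * raster$res^2 / area_ring, 1)
    return(w)
  }
  ring <- local_xy(geom$xy, raster$origin)
  w <- ring_weights(ring, raster)
  attr(w, "covered_frac") <- min(sum(w$w) * raster$res^2 / ring_area(ring), 1)
  w
}

ring_weights <- function(ring, raster) {
  res <- raster$res
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  bb <- bbox_of(ring)
  c0 <- max(1L, floor((bb[1] - raster$xmin) / res) + 1L)
  c1 <- min(nc, ceiling((bb[3] - raster$xmin) / res))
  rymax <- raster_ymax(raster)
  r0 <- max(1L, floor((rymax - bb[4]) / res) + 1L)
  r1 <- min(nr, ceiling((rymax - bb[2]) / res))
  if (c0 > c1 || r0 > r1) {
    return(tibble::tibble(row = integer(0), col = integer(0), w = numeric(0)))
  }
  cols <- c0:c1; rows <- r0:r1
  nco <- length(cols); nro <- length(rows)
  convex <- ring_is_convex(ring)
  ring_ccw <- ensure_ccw(ring)
  # corner-lattice inside flags enable fast interior/exterior paths for
  # convex rings; a wholly-outside cell with no ring vertex inside it can
  # only be crossed by a slab thinner than a cell, so the skip is exact
  # whenever the ring is at least two cells wide
  xs <- raster$xmin + (c(cols, c1 + 1L) - 1L) * res
  ys <- rymax - (c(rows, r1 + 1L) - 1L) * res
  if (convex) {
    gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
    inside <- matrix(points_in_ring(gx, gy, ring), nrow = length(xs))
    corners_in <- inside[seq_len(nco), seq_len(nro), drop = FALSE] +
      inside[seq_len(nco) + 1L, seq_len(nro), drop = FALSE] +
      inside[seq_len(nco), seq_len(nro) + 1L, drop = FALSE] +
      inside[seq_len(nco) + 1L, seq_len(nro) + 1L, drop = FALSE]
    has_vertex <- matrix(FALSE, nco, nro)
    vc <- floor((ring[, 1] - raster$xmin) / res) + 1L - c0 + 1L
    vr <- floor((rymax - ring[, 2]) / res) + 1L - r0 + 1L
    okv <- vc >= 1 & vc <= nco & vr >= 1 & vr <= nro
    has_vertex[cbind(vc[okv], vr[okv])] <- TRUE
    skip_safe <- min(bb[3] - bb[1], bb[4] - bb[2]) > 2 * res
  }
  cap <- nco * nro
  out_row <- integer(cap); out_col <- integer(cap); out_w <- numeric(cap)
  k <- 0L
  for (ri in seq_len(nro)) {
    ytop <- rymax - (rows[ri] - 1L) * res; ybot <- ytop - res
    for (ci in seq_len(nco)) {
      if (convex) {
        nin <- corners_in[ci, ri]
        if (nin == 4L) {
          k <- k + 1L
          out_row[k] <- rows[ri]; out_col[k] <- cols[ci]; out_w[k] <- 1
          next
        }
        if (nin == 0L && !has_vertex[ci, ri] && skip_safe) next
      }
      xleft <- raster$xmin + (cols[ci] - 1L) * res
      cellrect <- cbind(c(xleft, xleft + res, xleft + res, xleft),
                        c(ybot, ybot, ytop, ytop))
      wcell <- ring_area(clip_polygon_convex(ring_ccw, cellrect)) / res^2
      if (wcell > 1e-12) {
        k <- k + 1L
        out_row[k] <- rows[ri]; out_col[k] <- cols[ci]; out_w[k] <- min(wcell, 1)
      }
    }
  }
  tibble::tibble(row = out_row[seq_len(k)], col = out_col[seq_len(k)],
                 w = out_w[seq_len(k)])
}

# Weighted zonal summary of raster values over a geometry.
zonal_values <- function(geom, raster) {
  w <- cell_weights(geom, raster)
  v <- raster$values[cbind(w$row, w$col)]
  list(values = v, weights = w$w, covered_frac = attr(w, "covered_frac"),
       cells = w)
}
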