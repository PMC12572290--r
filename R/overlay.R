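# Per-site overlay quantities feeding the integrity score: built-up
# fraction, road metrics, tree-cover-at-planting, land-cover and stable-
# cropland fractions, loss-year window fractions, terrain statistics.

#' Fraction of a site covered by given raster classes
#'
#' Area-weighted at the cell level: each cell contributes its exact
#' intersection area with the polygon. A site entirely outside the raster
#' yields `NA` with a warning; partial overlap computes the fraction over
#' the covered part and reports the coverage ratio as an attribute.
#'
#' @param geom an `ldis_geom` polygon or annulus.
#' @param raster a categorical `ldis_raster`.
#' @param classes vector of class codes counted as "in" (empty set gives 0).
#' @return A ratio in `[0, 1]` (or `NA`), with attribute `covered_frac`.
#' @export
class_fraction <- function(geom, raster, classes) {
  fraction_from_zonal(zonal_values(geom, raster), classes)
}

fraction_from_zonal <- function(z, classes) {
  if (!length(z$values)) {
    warning("site does not overlap the raster extent", call. = FALSE)
    return(structure(NA_real_, covered_frac = 0))
  }
  if (z$covered_frac < 0.999) {
    warning(sprintf("site only %.1f%% covered by raster; fraction computed over covered part",
                    100 * z$covered_frac), call. = FALSE)
  }
  ok <- !is.na(z$values)
  if (!any(ok)) return(structure(NA_real_, covered_frac = z$covered_frac))
  f <- if (!length(classes)) 0 else {
    sum(z$weights[ok & z$values %in% classes]) / sum(z$weights[ok])
  }
  structure(f, covered_frac = z$covered_frac)
}

#' Road length, density and cover fraction within a site
#'
#' Clips each road line to the site ring in a local metric frame
#' (Cyrus-Beck for convex rings; midpoint-subdivision for concave ones),
#' sums geodesic segment lengths, and converts length to covered area via
#' the configured corridor width (`road_cover = length x width / area`,
#' capped at 1; corridor self-overlap is not de-duplicated).
#'
#' @param geom an `ldis_geom` polygon.
#' @param roads tibble with a `geometry` list column of linestrings (or a
#'   bare list of linestrings); `NULL`/empty gives zeros.
#' @param cfg a [ldis_config()].
#' @return A list: `road_length_km`, `road_density_km_per_km2`,
#'   `road_cover_fraction`.
#' @export
road_metrics <- function(geom, roads, cfg = ldis_config()) {
  area <- geo_area_km2(geom)
  zero <- list(road_length_km = 0, road_density_km_per_km2 = 0, road_cover_fraction = 0)
  if (is.null(roads)) return(zero)
  lines <- if (is.data.frame(roads)) roads$geometry else roads
  if (!length(lines)) return(zero)
  origin <- geom_anchor(geom)
  ring <- local_xy(geom$xy, origin)
  convex <- ring_is_convex(ring)
  total_m <- 0
  for (ln in lines) {
    pts <- local_xy(ln$xy, origin)
    for (s in seq_len(nrow(pts) - 1L)) {
      p0 <- pts[s, ]; p1 <- pts[s + 1L, ]
      if (convex) {
        cl <- clip_segment_convex(p0, p1, ring)
        if (!is.null(cl)) {
          ll <- lonlat_xy(cl, origin)
          total_m <- total_m + geosphere::distGeo(ll[1, ], ll[2, ])
        }
      } else {
        k <- 64L
        t0 <- (seq_len(k) - 1) / k; t1 <- seq_len(k) / k
        mx <- p0[1] + (t0 + t1) / 2 * (p1[1] - p0[1])
        my <- p0[2] + (t0 + t1) / 2 * (p1[2] - p0[2])
        frac <- mean(points_in_ring(mx, my, ring))
        if (frac > 0) {
          ll <- lonlat_xy(rbind(p0, p1), origin)
          total_m <- total_m + frac * geosphere::distGeo(ll[1, ], ll[2, ])
        }
      }
    }
  }
  len_km <- total_m / 1000
  list(road_length_km = len_km,
       road_density_km_per_km2 = len_km / area,
       road_cover_fraction = min(len_km * (cfg$road_corridor_width_m / 1000) / area, 1))
}

#' Tree-cover-loss fractions around the planting date
#'
#' From a loss-year raster (cell value = calendar year of first loss, 0 for
#' none), computes the site fraction lost in the five years before planting,
#' in the year immediately preceding planting, and in the five years after
#' planting. Post windows extending past the raster's last encoded year are
#' truncated with a flag; an empty post window yields `NA`.
#'
#' @param geom an `ldis_geom` polygon.
#' @param lossyear an `ldis_raster` with meta `year_min`, `year_max`.
#' @param planting_year integer year, or `NA` (all fractions `NA`).
#' @return A list: `loss_frac_pre5`, `loss_frac_pre1`, `loss_frac_post5`,
#'   `post5_truncated`.
#' @export
loss_window_fractions <- function(geom, lossyear, planting_year) {
  loss_windows_from_zonal(zonal_values(geom, lossyear), lossyear, planting_year)
}

loss_windows_from_zonal <- function(z, lossyear, planting_year) {
  if (is.na(planting_year)) {
    return(list(loss_frac_pre5 = NA_real_, loss_frac_pre1 = NA_real_,
                loss_frac_post5 = NA_real_, post5_truncated = FALSE))
  }
  y_max <- lossyear$meta$year_max %||% max(lossyear$values[lossyear$values > 0], -Inf)
  pre5 <- fraction_from_zonal(z, seq(planting_year - 5, planting_year - 1))
  pre1 <- fraction_from_zonal(z, planting_year - 1)
  post_end <- min(planting_year + 5, y_max)
  truncated <- post_end < planting_year + 5
  post5 <- if (post_end < planting_year + 1) {
    NA_real_
  } else {
    as.numeric(fraction_from_zonal(z, seq(planting_year + 1, post_end)))
  }
  list(loss_frac_pre5 = as.numeric(pre5), loss_frac_pre1 = as.numeric(pre1),
       loss_frac_post5 = post5, post5_truncated = truncated)
}

# Horn's 3x3 finite-difference slope, degrees, edge rows replicated.
horn_slope_deg <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  pad <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  sh <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  # rows run north->south: +dr moves south, so dz/dy needs a sign flip
  gx <- ((sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
           (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))) / (8 * dem$res)
  gy <- ((sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1)) -
           (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1))) / (8 * dem$res)
  atan(sqrt(gx^2 + gy^2)) * 180 / pi
}

#' Mean elevation and slope of a site
#'
#' Means over all DEM cells intersecting the site polygon; slope from
#' Horn's 3x3 finite-difference method on the metric-resolution DEM. A site
#' smaller than one cell inherits the statistics of its containing cell.
#'
#' @param geom an `ldis_geom` polygon.
#' @param dem an `ldis_raster` of elevations in metres.
#' @return A list: `mean_elevation_m`, `mean_slope_deg`.
#' @export
terrain_stats <- function(geom, dem) {
  w <- cell_weights(geom, dem)
  if (!nrow(w)) return(list(mean_elevation_m = NA_real_, mean_slope_deg = NA_real_))
  slope <- horn_slope_deg(dem)
  idx <- cbind(w$row, w$col)
  list(mean_elevation_m = mean(dem$values[idx], na.rm = TRUE),
       mean_slope_deg = mean(slope[idx], na.rm = TRUE))
}

#' Compute all overlay metrics for a site table
#'
#' Any layer may be `NULL`; its metrics come back `NA` (roads: zeros are
#' only reported when a road layer is supplied).
#'
#' @param sites a site tibble.
#' @param built binary `ldis_raster` (1 = built-up).
#' @param landcover categorical `ldis_raster`.
#' @param landcover_classes named list mapping `treecover`, `other`,
#'   `cropland`, `water` to class-code vectors.
#' @param lossyear loss-year `ldis_raster`.
#' @param roads road layer (see [road_metrics()]).
#' @param dem elevation `ldis_raster`.
#' @param cfg a [ldis_config()].
#' @return A tibble with one row per site and the overlay-metric columns.
#' @export
overlay_metrics <- function(sites, built = NULL, landcover = NULL,
                            landcover_classes = list(treecover = 1, other = 2,
                                                     cropland = 3, water = 4),
                            lossyear = NULL, roads = NULL, dem = NULL,
                            cfg = ldis_config()) {
  purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    g <- sites$geometry_derived[[i]]
    out <- list(site_id = sites$site_id[i],
                built_fraction = NA_real_, road_length_km = NA_real_,
                road_density_km_per_km2 = NA_real_, road_cover_fraction = NA_real_,
                treecover_at_planting_fraction = NA_real_,
                other_landcover_fraction = NA_real_,
                stable_cropland_fraction = NA_real_,
                permanent_water_fraction = NA_real_,
                loss_frac_pre5 = NA_real_, loss_frac_pre1 = NA_real_,
                loss_frac_post5 = NA_real_,
                mean_elevation_m = NA_real_, mean_slope_deg = NA_real_)
    if (!is.null(built)) out$built_fraction <- as.numeric(class_fraction(g, built, 1))
    if (!is.null(landcover)) {
      z <- zonal_values(g, landcover)
      out$treecover_at_planting_fraction <-
        as.numeric(fraction_from_zonal(z, landcover_classes$treecover))
      out$other_landcover_fraction <-
        as.numeric(fraction_from_zonal(z, landcover_classes$other))
      out$stable_cropland_fraction <-
        as.numeric(fraction_from_zonal(z, landcover_classes$cropland))
      out$permanent_water_fraction <-
        as.numeric(fraction_from_zonal(z, landcover_classes$water))
    }
    if (!is.null(lossyear)) {
      lw <- loss_windows_from_zonal(zonal_values(g, lossyear), lossyear,
                                    sites$planting_year[i] %||% NA)
      out[c("loss_frac_pre5", "loss_frac_pre1", "loss_frac_post5")] <-
        lw[c("loss_frac_pre5", "loss_frac_pre1", "loss_frac_post5")]
    }
    if (!is.null(roads)) out[names(road_metrics(g, NULL))] <- road_metrics(g, roads, cfg)
    if (!is.null(dem)) out[c("mean_elevation_m", "mean_slope_deg")] <- terrain_stats(g, dem)
    tibble::as_tibble(out)
  })
}
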