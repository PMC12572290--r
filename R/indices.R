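# Vegetation indices (NDVI, NDRE, SAVI), cloud filtering, greenest-month
# compositing, and site/annulus index panels per period.

PANEL_PERIODS <- c("minus1", "at_planting", "plus1", "plus2", "plus5")
PERIOD_OFFSETS <- c(minus1 = -1L, at_planting = 0L, plus1 = 1L, plus2 = 2L, plus5 = 5L)

#' Normalized Difference Vegetation Index
#'
#' `(nir - red) / (nir + red)`; in `[-1, 1]` for nonnegative reflectances.
#' Zero denominators yield `NA`.
#'
#' @param nir,red reflectances in `[0, 1]` (vectorized).
#' @return Numeric vector of index values.
#' @examples
#' ndvi(0.6, 0.2)  # 0.5
#' @export
ndvi <- function(nir, red) {
  den <- nir + red
  ifelse(den == 0, NA_real_, (nir - red) / den)
}

#' Normalized Difference Red Edge index
#'
#' `(nir - red_edge) / (nir + red_edge)`; sensitive to chlorophyll and
#' subtle stress in trees.
#'
#' @param nir,red_edge reflectances in `[0, 1]` (vectorized).
#' @return Numeric vector of index values.
#' @export
ndre <- function(nir, red_edge) {
  den <- nir + red_edge
  ifelse(den == 0, NA_real_, (nir - red_edge) / den)
}

#' Soil-Adjusted Vegetation Index
#'
#' Default formula as published here:
#' `(nir - red_edge) / (nir + red_edge + L) * (1 + L)` with `L = 0.5` and
#' the red-edge band. The conventional SAVI uses the red band instead;
#' `use_red = TRUE` switches to it (supply `red`). Both the soil constant
#' and the multiplier follow from `L`.
#'
#' @param nir,red_edge,red reflectances in `[0, 1]` (vectorized).
#' @param L soil-brightness correction constant (default 0.5).
#' @param use_red use the red band in place of red-edge.
#' @return Numeric vector of index values.
#' @examples
#' savi(0.6, 0.2)  # (0.4 / 1.3) * 1.5
#' @export
savi <- function(nir, red_edge = NULL, red = NULL, L = 0.5, use_red = FALSE) {
  band <- if (use_red) red else red_edge
  if (is.null(band)) stop("supply red_edge (default) or red with use_red = TRUE", call. = FALSE)
  den <- nir + band + L
  ifelse(den == 0, NA_real_, (nir - band) / den * (1 + L))
}

#' Cloud fraction of a scene over a site footprint
#'
#' @param mask cloud-mask `ldis_raster` (nonzero = cloudy).
#' @param geom an `ldis_geom` polygon or annulus.
#' @param cfg a [ldis_config()]; a composite is retained iff the fraction is
#'   strictly below `cfg$cloud_frac_max`.
#' @return A list: `fraction`, `retain`.
#' @export
cloud_fraction <- function(mask, geom, cfg = ldis_config()) {
  if (is.null(mask)) {
    warning("no cloud-mask band: composite retained unfiltered", call. = FALSE)
    return(list(fraction = NA_real_, retain = TRUE))
  }
  z <- zonal_values(geom, mask)
  if (!length(z$values)) return(list(fraction = NA_real_, retain = TRUE))
  f <- sum(z$weights[z$values != 0]) / sum(z$weights)
  list(fraction = f, retain = f < cfg$cloud_frac_max)
}

#' Select the greenest months from a monthly NDVI series
#'
#' Picks the `k` months with highest NDVI; ties break toward the earlier
#' calendar month; missing months are excluded. A fixed regional month list
#' (e.g. Jan/Apr/May for Africa) bypasses selection entirely.
#'
#' @param monthly_ndvi numeric vector of 12 monthly NDVI means (NA allowed).
#' @param k number of months to keep.
#' @param override optional integer months (1-12) returned as-is.
#' @return Sorted integer vector of selected months.
#' @examples
#' greenest_months(seq(0.1, 0.65, length.out = 12))  # 10 11 12
#' @export
greenest_months <- function(monthly_ndvi, k = 3, override = NULL) {
  if (!is.null(override)) return(sort(as.integer(override)))
  stopifnot(length(monthly_ndvi) == 12)
  avail <- which(!is.na(monthly_ndvi))
  if (length(avail) < k) {
    warning("fewer than k non-missing months; returning all available", call. = FALSE)
    return(avail)
  }
  ord <- avail[order(-monthly_ndvi[avail], avail)]
  sort(ord[seq_len(k)])
}

same_grid <- function(a, b) {
  a$xmin == b$xmin && a$ymin == b$ymin && a$res == b$res &&
    all(dim(a$values) == dim(b$values))
}

# Zonal index means of one scene over one zone geometry; `w` is a
# precomputed cell_weights() table valid for the scene's grid.
scene_zonal <- function(geom, scene, w = NULL) {
  if (is.null(w)) w <- cell_weights(geom, scene$nir)
  if (!nrow(w)) return(NULL)
  idx <- cbind(w$row, w$col)
  zn <- list(values = scene$nir$values[idx], weights = w$w)
  red <- scene$red$values[idx]
  re <- scene$red_edge$values[idx]
  nirv <- zn$values
  ok <- !is.na(nirv) & !is.na(red)
  if (!is.null(scene$cloud)) ok <- ok & (scene$cloud$values[idx] == 0)
  if (!any(ok)) return(NULL)
  w <- zn$weights[ok]
  list(ndvi = sum(w * ndvi(nirv[ok], red[ok])) / sum(w),
       ndre = sum(w * ndre(nirv[ok], re[ok])) / sum(w),
       savi = sum(w * savi(nirv[ok], re[ok])) / sum(w),
       n_valid_cells = sum(ok))
}

#' Build the site/annulus vegetation-index panel
#'
#' For every site with a known planting year, every zone (site polygon and
#' its 500 m annulus) and every period with at least one retained scene:
#' scenes are cloud-filtered over the site footprint (fraction strictly
#' below `cfg$cloud_frac_max`), the `cfg$greenest_k` scenes with highest
#' site-level NDVI are composited (median by default), and zonal
#' area-weighted means of NDVI/NDRE/SAVI are recorded together with the
#' number of valid cells. Periods without scenes simply yield no rows
#' (balancing is the analysis step's job).
#'
#' @param sites a site tibble.
#' @param scenes tibble with columns `period`, `year`, optional `month`,
#'   and list columns `nir`, `red`, `red_edge`, `cloud` of `ldis_raster`s.
#' @param cfg a [ldis_config()].
#' @return A tibble: `site_id`, `zone` ("site"/"annulus"), `period`,
#'   `year`, `ndvi`, `ndre`, `savi`, `n_valid_cells`.
#' @export
build_panel <- function(sites, scenes, cfg = ldis_config()) {
  no_year <- is.na(sites$planting_year)
  if (any(no_year)) {
    message(sum(no_year), " site(s) without planting year skipped")
  }
  invalid <- !vapply(sites$geometry_derived, validate_geometry, logical(1))
  if (any(invalid)) {
    message(sum(invalid), " site(s) with invalid geometry skipped")
  }
  rows <- list()
  for (i in which(!no_year & !invalid)) {
    g_site <- sites$geometry_derived[[i]]
    g_ann <- make_annulus(g_site, cfg)
    w_site <- NULL; w_ann <- NULL; w_grid <- NULL
    for (per in intersect(PANEL_PERIODS, unique(scenes$period))) {
      cand <- scenes[scenes$period == per, ]
      if (!nrow(cand)) next
      stats_site <- list(); stats_ann <- list()
      for (s in seq_len(nrow(cand))) {
        scene <- list(nir = cand$nir[[s]], red = cand$red[[s]],
                      red_edge = cand$red_edge[[s]],
                      cloud = if ("cloud" %in% names(cand)) cand$cloud[[s]] else NULL)
        if (is.null(w_grid) || !same_grid(w_grid, scene$nir)) {
          w_site <- cell_weights(g_site, scene$nir)
          w_ann <- cell_weights(g_ann, scene$nir)
          w_grid <- scene$nir
        }
        if (!is.null(scene$cloud)) {
          idx <- cbind(w_site$row, w_site$col)
          cfrac <- sum(w_site$w[scene$cloud$values[idx] != 0]) / sum(w_site$w)
          if (!is.na(cfrac) && cfrac >= cfg$cloud_frac_max) next
        }
        zs <- scene_zonal(g_site, scene, w_site)
        if (is.null(zs)) next
        za <- scene_zonal(g_ann, scene, w_ann)
        stats_site[[length(stats_site) + 1L]] <- zs
        stats_ann[[length(stats_ann) + 1L]] <- za
      }
      if (!length(stats_site)) next
      ndvis <- vapply(stats_site, `[[`, numeric(1), "ndvi")
      keep <- order(-ndvis)[seq_len(min(cfg$greenest_k, length(ndvis)))]
      agg <- if (cfg$composite_stat == "median") stats::median else mean
      comp <- function(stats_list, fld) agg(vapply(stats_list[keep], function(s)
        if (is.null(s)) NA_real_ else s[[fld]], numeric(1)), na.rm = TRUE)
      yr <- sites$planting_year[i] + PERIOD_OFFSETS[[per]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        site_id = sites$site_id[i],
        zone = c("site", "annulus"),
        period = per, year = yr,
        ndvi = c(comp(stats_site, "ndvi"), comp(stats_ann, "ndvi")),
        ndre = c(comp(stats_site, "ndre"), comp(stats_ann, "ndre")),
        savi = c(comp(stats_site, "savi"), comp(stats_ann, "savi")),
        n_valid_cells = c(stats_site[[keep[1]]]$n_valid_cells,
                          if (is.null(stats_ann[[keep[1]]])) 0L else
                            stats_ann[[keep[1]]]$n_valid_cells))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(site_id = character(0), zone = character(0),
                          period = character(0), year = integer(0),
                          ndvi = numeric(0), ndre = numeric(0), savi = numeric(0),
                          n_valid_cells = integer(0))
  }
  dplyr::filter(out, !is.na(.data$ndvi))
}
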