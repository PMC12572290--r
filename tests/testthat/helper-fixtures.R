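# Shared fixtures, all built in code. The local frame is anchored near the
# equator so degrees and metres convert without latitude surprises.

FIX_ORIGIN <- c(37.0, -0.5)

# polygon from local metric coordinates (metres about FIX_ORIGIN)
local_poly <- function(xy, origin = FIX_ORIGIN) {
  geo_polygon(ldiscore:::lonlat_xy(as.matrix(xy), origin))
}

local_line <- function(xy, origin = FIX_ORIGIN) {
  geo_linestring(ldiscore:::lonlat_xy(as.matrix(xy), origin))
}

# axis-aligned square of side `side` metres with lower-left corner at (x0, y0)
local_square <- function(x0, y0, side, origin = FIX_ORIGIN) {
  local_poly(cbind(c(x0, x0 + side, x0 + side, x0),
                   c(y0, y0, y0 + side, y0 + side)), origin)
}

# minimal site tibble around a list of geometries
site_table <- function(geoms, ids = sprintf("s%02d", seq_along(geoms)),
                       planting_year = 2018L, cfg = ldis_config()) {
  tab <- tibble::tibble(
    site_id = ids,
    project_id_reported = NA_character_, host_name = NA_character_,
    url = NA_character_, iso3 = NA_character_,
    geometry_kind = ifelse(vapply(geoms, function(g) g$type, character(1)) == "point",
                           "point", "polygon"),
    geometry_reported = geoms,
    planting_date_reported = as.Date(sprintf("%d-03-15", planting_year)),
    planting_date_type = "planting",
    planting_year = as.integer(planting_year),
    area_reported_km2 = NA_real_)
  derive_geometries(tab, cfg)
}

# all-zero overlay metrics (every raster indicator passes)
zero_metrics <- function(site_ids) {
  tibble::tibble(site_id = site_ids, built_fraction = 0, road_length_km = 0,
                 road_density_km_per_km2 = 0, road_cover_fraction = 0,
                 treecover_at_planting_fraction = 0, other_landcover_fraction = 0,
                 stable_cropland_fraction = 0, permanent_water_fraction = 0,
                 loss_frac_pre5 = 0, loss_frac_pre1 = 0, loss_frac_post5 = 0,
                 mean_elevation_m = 500, mean_slope_deg = 0)
}

# a full indicator map
indicator_map <- function(status = "pass") {
  stats::setNames(rep(status, 10), ldis_indicator_names())
}

expect_close <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol)
}
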