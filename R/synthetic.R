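# Seeded synthetic inputs with the structure the pipeline assumes: site
# tables with injected pathologies (near-perfect circles, admin copies,
# duplicates, nested children, partial overlaps, invalid rings, bare
# points), overlay rasters with known painted fractions, reflectance stacks
# whose NDVI trajectories are hit exactly by construction, and balanced 2x2
# DiD panels with the published regression presets.

#' Scenario configuration for the synthetic generators
#'
#' Defaults describe a small Kenyan-style landscape: sites of 100-250 m
#' nominal radius laid out on a 2.5 km grid so that no 500 m annulus
#' touches a neighbouring site; a pre-planting clearing dip of 0.10 NDVI
#' followed by recovery of 0.02 NDVI/year; a background (annulus) NDVI of
#' 0.30 with 30% spillover of the site trend.
#'
#' @param rng_seed integer seed; every generator is a pure function of it.
#' @param n_sites number of base sites.
#' @param frac_points,frac_circles,frac_admin_copies composition fractions
#'   (the remainder are irregular convex polygons); must sum to <= 1.
#' @param dup_rate,nest_rate,intersect_rate,invalid_rate rates of injected
#'   pathologies among polygon sites.
#' @param viol_rates named rates of injected overlay violations
#'   (`road`, `built`, `landcover`) among relation-free sites.
#' @param raster_res_m,reflect_res_m cell sizes of overlay and reflectance
#'   rasters, metres.
#' @param spacing_m site grid spacing, metres.
#' @param radius_range_m nominal site radius range, metres.
#' @param origin lon/lat anchoring the local frame.
#' @param planting_year common planting year.
#' @param ndvi_site_pre,ndvi_annulus baseline NDVI levels.
#' @param clearing_dip NDVI drop from the pre-planting year to planting.
#' @param growth_rate NDVI gain per year after planting.
#' @param spillover fraction of the site trend leaking into the annulus.
#' @param cloud_rate fraction of scene cells flagged cloudy.
#' @param did_params generator preset for [gen_did_panel()] (see
#'   [did_preset()]).
#' @return A list of class `ldis_scenario`.
#' @export
ldis_scenario <- function(rng_seed = 1L, n_sites = 50L,
                          frac_points = 0.2, frac_circles = 0.2,
                          frac_admin_copies = 0.1,
                          dup_rate = 0.1, nest_rate = 0.1,
                          intersect_rate = 0.1, invalid_rate = 0.05,
                          viol_rates = c(road = 0.2, built = 0.2, landcover = 0.3),
                          raster_res_m = 20, reflect_res_m = 25,
                          spacing_m = 2500, radius_range_m = c(100, 250),
                          origin = c(37.0, -0.5), planting_year = 2018L,
                          ndvi_site_pre = 0.35, ndvi_annulus = 0.30,
                          clearing_dip = 0.10, growth_rate = 0.02,
                          spillover = 0.3, cloud_rate = 0,
                          did_params = did_preset("table6_col2")) {
  if (any(c(frac_points, frac_circles, frac_admin_copies) < 0) ||
      frac_points + frac_circles + frac_admin_copies > 1) {
    stop("frac_points + frac_circles + frac_admin_copies must lie in [0, 1]", call. = FALSE)
  }
  structure(as.list(environment()), class = c("ldis_scenario", "list"))
}

#' Published DiD generator presets
#'
#' Coefficients, residual SD and sample size of the four reported
#' regressions (outcome NDVI; periods relative to the planting date). The
#' pre-planting model treats the planting date itself as "after" and the
#' year before as baseline.
#'
#' @param name one of `"table6_col1"` ... `"table6_col4"`.
#' @return A list: `intercept`, `beta_g`, `beta_t`, `beta_gt`,
#'   `residual_sd`, `n_obs`, `baseline`, `period_after`, `r2`.
#' @export
did_preset <- function(name = c("table6_col1", "table6_col2",
                                "table6_col3", "table6_col4")) {
  name <- match.arg(name)
  switch(name,
    table6_col1 = list(intercept = 0.290, beta_g = -0.105, beta_t = 0.038,
                       beta_gt = 0.038, residual_sd = 0.208, n_obs = 139248L,
                       baseline = "minus1", period_after = "at_planting",
                       r2 = 0.061),
    table6_col2 = list(intercept = 0.265, beta_g = -0.090, beta_t = 0.048,
                       beta_gt = 0.048, residual_sd = 0.170, n_obs = 469500L,
                       baseline = "at_planting", period_after = "plus1",
                       r2 = 0.081),
    table6_col3 = list(intercept = 0.265, beta_g = -0.090, beta_t = 0.068,
                       beta_gt = 0.059, residual_sd = 0.181, n_obs = 469500L,
                       baseline = "at_planting", period_after = "plus2",
                       r2 = 0.097),
    table6_col4 = list(intercept = 0.265, beta_g = -0.090, beta_t = 0.091,
                       beta_gt = 0.074, residual_sd = 0.184, n_obs = 469500L,
                       baseline = "at_planting", period_after = "plus5",
                       r2 = 0.132))
}

# Random elongated convex ring (metres, centred on 0) with circularity
# safely below the perfect-circle threshold.
rand_convex_ring <- function(r, k = 10L) {
  th <- sort(stats::runif(k, 0, 2 * pi))
  rad <- r * stats::runif(k, 0.7, 1.3)
  elong <- stats::runif(1, 1.7, 2.4)
  xy <- cbind(elong * rad * cos(th), rad * sin(th))
  xy[grDevices::chull(xy), , drop = FALSE]
}

#' Generate a synthetic site table with known integrity pathologies
#'
#' Lays base sites out on a grid (no accidental interactions), injects the
#' configured mix of bare points, near-perfect circles, exact admin copies,
#' bow-tie (invalid) rings, duplicates (>95% mutual overlap), nested
#' children and ~30%-overlap partners, and records per site which
#' integrity indicator each pathology must trip.
#'
#' @param scn an [ldis_scenario()].
#' @return A list: `sites` (site tibble), `admins` (admin tibble), `truth`
#'   (tibble of expected indicator outcomes per site).
#' @export
gen_sites <- function(scn) {
  withr::with_seed(scn$rng_seed, gen_sites_impl(scn))
}

gen_sites_impl <- function(scn) {
  n <- scn$n_sites
  n_pt <- round(scn$frac_points * n)
  n_ci <- round(scn$frac_circles * n)
  n_ad <- round(scn$frac_admin_copies * n)
  n_inv <- round(scn$invalid_rate * n)
  kinds <- sample(c(rep("point", n_pt), rep("circle", n_ci), rep("admin", n_ad),
                    rep("invalid", min(n_inv, n - n_pt - n_ci - n_ad)),
                    rep("polygon", max(0, n - n_pt - n_ci - n_ad - n_inv))))

  # grid layout in the local metric frame
  ncol_grid <- ceiling(sqrt(n * 1.6))
  cells <- seq_len(ncol_grid^2)
  slots <- sample(cells, n)
  centers <- cbind(((slots - 1) %% ncol_grid + 0.5) * scn$spacing_m,
                   ((slots - 1) %/% ncol_grid + 0.5) * scn$spacing_m)

  # admin regions: one per admin-copy site plus two decoys, placed on the
  # same grid in unused slots
  n_adm <- n_ad + 2L
  adm_slots <- sample(setdiff(cells, slots), n_adm)
  adm_centers <- cbind(((adm_slots - 1) %% ncol_grid + 0.5) * scn$spacing_m,
                       ((adm_slots - 1) %/% ncol_grid + 0.5) * scn$spacing_m)
  adm_rings <- lapply(seq_len(n_adm), function(i) {
    sweep(rand_convex_ring(mean(scn$radius_range_m) * 1.5), 2,
          adm_centers[i, ], "+")
  })
  admins <- tibble::tibble(
    admin_id = sprintf("adm%02d", seq_len(n_adm)),
    name = sprintf("region %02d", seq_len(n_adm)),
    level = 2L,
    geometry = lapply(adm_rings, function(r) geo_polygon(lonlat_xy(r, scn$origin))))

  rmin <- scn$radius_range_m[1]; rmax <- scn$radius_range_m[2]
  geoms <- vector("list", n)
  adm_used <- 0L
  for (i in seq_len(n)) {
    ctr <- centers[i, ]
    r <- stats::runif(1, rmin, rmax)
    ring <- switch(kinds[i],
      point = NULL,
      circle = sweep(disc_ring(c(0, 0), r, n = 48L), 2, ctr, "+"),
      admin = { adm_used <- adm_used + 1L; adm_rings[[adm_used]] },
      invalid = sweep(rbind(c(-r, -r), c(r, r), c(-r, r), c(r, -r)), 2, ctr, "+"),
      polygon = sweep(rand_convex_ring(r), 2, ctr, "+"))
    geoms[[i]] <- if (kinds[i] == "point") {
      geo_point(lonlat_xy(matrix(ctr, ncol = 2), scn$origin)[1],
                lonlat_xy(matrix(ctr, ncol = 2), scn$origin)[2])
    } else geo_polygon(lonlat_xy(ring, scn$origin))
  }

  base <- tibble::tibble(
    site_id = sprintf("s%04d", seq_len(n)),
    kind = kinds, geometry_reported = geoms,
    relation = "none", partner = NA_character_)

  # relations are injected among plain polygon sites only
  poly_idx <- which(base$kind == "polygon")
  pick <- function(pool, rate) {
    k <- min(length(pool), round(rate * n))
    if (k == 0) integer(0) else pool[seq_len(k)]
  }
  pool <- sample(poly_idx)
  dup_of <- pick(pool, scn$dup_rate); pool <- setdiff(pool, dup_of)
  nest_of <- pick(pool, scn$nest_rate); pool <- setdiff(pool, nest_of)
  int_of <- pick(pool, scn$intersect_rate)

  extra <- list()
  add_partner <- function(idx, ring_fn, tag) {
    for (i in idx) {
      ring0 <- local_xy(base$geometry_reported[[i]]$xy, scn$origin)
      new_ring <- ring_fn(ring0)
      extra[[length(extra) + 1L]] <<- tibble::tibble(
        site_id = paste0(base$site_id[i], "-", tag),
        kind = "polygon",
        geometry_reported = list(geo_polygon(lonlat_xy(new_ring, scn$origin))),
        relation = tag, partner = base$site_id[i])
    }
  }
  add_partner(dup_of, function(rg) sweep(rg, 2, c(1, 1), "+"), "dup")
  add_partner(nest_of, function(rg) {
    ctr <- ring_centroid(rg)
    sweep((rg - rep(ctr, each = nrow(rg))) * 0.4, 2, ctr, "+")
  }, "nest")
  add_partner(int_of, function(rg) {
    width <- diff(range(rg[, 1]))
    sweep(rg, 2, c(0.6 * width, 0), "+")
  }, "int")
  base$relation[dup_of] <- "dup_base"
  base$relation[nest_of] <- "nest_base"
  base$relation[int_of] <- "int_base"
  tab <- dplyr::bind_rows(base, dplyr::bind_rows(extra))

  tab$geometry_kind <- ifelse(tab$kind == "point", "point", "polygon")
  m <- nrow(tab)
  sites <- tibble::tibble(
    site_id = tab$site_id,
    project_id_reported = sprintf("p%03d", (seq_len(m) - 1L) %/% 5L + 1L),
    host_name = "synthetic-registry", url = "https://example.invalid",
    iso3 = "KEN",
    geometry_kind = tab$geometry_kind,
    geometry_reported = tab$geometry_reported,
    planting_date_reported = as.Date(sprintf("%d-03-15", scn$planting_year)),
    planting_date_type = "planting",
    planting_year = as.integer(scn$planting_year),
    area_reported_km2 = NA_real_)
  sites <- derive_geometries(sites, ldis_config(rng_seed = scn$rng_seed))

  # overlay violations only on relation-free, valid sites
  eligible <- which(tab$relation == "none" & tab$kind != "invalid")
  viol <- tibble::tibble(site_id = tab$site_id,
                         road_viol = FALSE, built_viol = FALSE,
                         lc_viol = NA_character_)
  vr <- scn$viol_rates
  viol$road_viol[eligible] <- stats::runif(length(eligible)) < vr[["road"]]
  viol$built_viol[eligible] <- stats::runif(length(eligible)) < vr[["built"]]
  lc_hit <- eligible[stats::runif(length(eligible)) < vr[["landcover"]]]
  viol$lc_viol[lc_hit] <- sample(c("treecover", "other", "cropland"),
                                 length(lc_hit), replace = TRUE)

  related <- tab$relation != "none"
  truth <- tibble::tibble(
    site_id = tab$site_id,
    expect_circle_fail = tab$kind %in% c("point", "circle"),
    expect_admin_fail = tab$kind == "admin",
    expect_validity_fail = tab$kind == "invalid",
    expect_nesting_fail = tab$relation %in% c("dup_base", "dup", "nest"),
    expect_intersecting_fail = tab$relation %in% c("int_base", "int"),
    expect_road_fail = viol$road_viol,
    expect_built_fail = viol$built_viol,
    expect_forest_fail = !is.na(viol$lc_viol) & viol$lc_viol == "treecover",
    expect_other_fail = !is.na(viol$lc_viol) & viol$lc_viol == "other",
    expect_cropland_fail = !is.na(viol$lc_viol) & viol$lc_viol == "cropland")
  list(sites = sites, admins = admins, truth = truth)
}

# Rows/cols of raster cells whose centres fall inside a ring.
cells_inside <- function(ring, raster) {
  res <- raster$res
  bb <- bbox_of(ring)
  nc <- ncol(raster$values); nr <- nrow(raster$values)
  rymax <- raster_ymax(raster)
  cols <- max(1L, floor((bb[1] - raster$xmin) / res)):min(nc, ceiling((bb[3] - raster$xmin) / res))
  rows <- max(1L, floor((rymax - bb[4]) / res)):min(nr, ceiling((rymax - bb[2]) / res))
  cx <- raster$xmin + (cols - 0.5) * res
  cy <- rymax - (rows - 0.5) * res
  grid <- cbind(rep(rows, each = length(cols)), rep(cols, times = length(rows)))
  px <- rep(cx, times = length(rows)); py <- rep(cy, each = length(cols))
  grid[points_in_ring(px, py, ring), , drop = FALSE]
}

#' Generate overlay rasters and road vectors matching a site table
#'
#' Paints the configured violations into a built raster, a categorical
#' land-cover raster (0 bare, 1 tree cover at planting, 2 other land
#' cover, 3 stable cropland, 4 water), a loss-year raster and a ramp DEM,
#' and lays enough road passes across road-violating sites to exceed the
#' 10% corridor-cover rule. Painted fractions are far from the decision
#' thresholds (0.45 for the 20% rules, 0.30 for the 10% rules) so one-cell
#' quantization cannot flip an indicator.
#'
#' @param scn an [ldis_scenario()].
#' @param gen the output of [gen_sites()].
#' @return A list: `built`, `landcover`, `lossyear`, `dem` (rasters) and
#'   `roads` (tibble with a `geometry` list column).
#' @export
gen_rasters <- function(scn, gen) {
  withr::with_seed(scn$rng_seed + 1L, gen_rasters_impl(scn, gen))
}

gen_rasters_impl <- function(scn, gen) {
  sites <- gen$sites
  truth <- gen$truth
  rings <- lapply(sites$geometry_derived, function(g)
    local_xy(if (g$type == "polygon") g$xy else g$xy, scn$origin))
  allxy <- do.call(rbind, rings)
  pad <- 1000
  xmin <- floor(min(allxy[, 1]) - pad); ymin <- floor(min(allxy[, 2]) - pad)
  xmax <- ceiling(max(allxy[, 1]) + pad); ymax <- ceiling(max(allxy[, 2]) + pad)
  res <- scn$raster_res_m
  nc <- ceiling((xmax - xmin) / res); nr <- ceiling((ymax - ymin) / res)
  if (res > min(scn$radius_range_m)) {
    warning("raster resolution coarser than the smallest nominal site radius",
            call. = FALSE)
  }
  blank <- function(fill = 0) ldis_raster(matrix(fill, nr, nc), xmin, ymin, res, scn$origin)
  built <- blank(); landcover <- blank(); lossyear <- blank()
  lossyear$meta <- list(year_min = 2001L, year_max = 2023L)

  paint <- function(raster, cells, frac, value) {
    if (!nrow(cells)) return(raster)
    ord <- order(cells[, 2], cells[, 1])
    k <- ceiling(frac * nrow(cells))
    sel <- cells[ord[seq_len(k)], , drop = FALSE]
    raster$values[sel] <- value
    raster
  }

  road_lines <- list()
  for (i in seq_len(nrow(sites))) {
    ring <- rings[[i]]
    if (truth$expect_validity_fail[i]) next
    cells <- cells_inside(ring, built)
    tr <- truth[i, ]
    if (tr$expect_built_fail) built <- paint(built, cells, 0.30, 1)
    lc_code <- if (tr$expect_forest_fail) 1 else if (tr$expect_other_fail) 2 else
      if (tr$expect_cropland_fail) 3 else NA
    if (!is.na(lc_code)) landcover <- paint(landcover, cells, 0.45, lc_code)
    if (tr$expect_road_fail) {
      area_km2 <- sites$area_derived_km2[i]
      bb <- bbox_of(ring)
      span <- bb[3] - bb[1]
      # 2x the length needed to clear the 10% corridor rule
      need_km <- 2 * 0.10 * area_km2 / (ldis_config()$road_corridor_width_m / 1000)
      n_pass <- max(2L, ceiling(need_km * 1000 / (0.8 * span)))
      ys <- seq(bb[2] + 0.25 * (bb[4] - bb[2]), bb[4] - 0.25 * (bb[4] - bb[2]),
                length.out = n_pass)
      for (y in ys) {
        seg <- rbind(c(bb[1] - 100, y), c(bb[3] + 100, y))
        road_lines[[length(road_lines) + 1L]] <-
          geo_linestring(lonlat_xy(seg, scn$origin))
      }
    }
    # pre-planting loss on a stripe of non-violating valid sites, for the
    # loss-window metrics (not an LDIS indicator)
    if (!tr$expect_built_fail && is.na(lc_code) && stats::runif(1) < 0.3) {
      lossyear <- paint(lossyear, cells, 0.40, scn$planting_year - 1L)
    }
  }
  dem_vals <- outer(seq_len(nr), seq_len(nc), function(r, c) 500 + c * res / 90)
  dem <- ldis_raster(dem_vals, xmin, ymin, res, scn$origin)
  roads <- tibble::tibble(road_id = sprintf("r%03d", seq_along(road_lines)),
                          geometry = road_lines)
  list(built = built, landcover = landcover, lossyear = lossyear, dem = dem,
       roads = roads)
}

# NDVI trajectory implied by the scenario, per period.
scenario_ndvi <- function(scn) {
  off <- PERIOD_OFFSETS
  site <- c(minus1 = scn$ndvi_site_pre,
            at_planting = scn$ndvi_site_pre - scn$clearing_dip,
            plus1 = scn$ndvi_site_pre - scn$clearing_dip + scn$growth_rate * 1,
            plus2 = scn$ndvi_site_pre - scn$clearing_dip + scn$growth_rate * 2,
            plus5 = scn$ndvi_site_pre - scn$clearing_dip + scn$growth_rate * 5)
  ann <- scn$ndvi_annulus + scn$spillover * (site - site[["minus1"]])
  list(site = site, annulus = ann)
}

#' Generate per-period reflectance stacks for a site table
#'
#' One scene per period over the whole scenario extent. Bands are
#' synthesized by inverting the index formulas (`nir + red = 1`, so
#' `NDVI = nir - red` exactly, and `red_edge = red` so NDRE equals NDVI):
#' painted cells hit the target NDVI trajectory exactly, making zonal-mean
#' tests sharp. Site interiors follow the pre-planting level, the clearing
#' dip at planting and linear recovery; the background (annulus) carries
#' its own baseline plus the configured spillover of the site trend.
#'
#' @param scn an [ldis_scenario()].
#' @param gen the output of [gen_sites()].
#' @return A scenes tibble for [build_panel()]: `period`, `year`, and
#'   raster list columns `nir`, `red`, `red_edge`, `cloud`.
#' @export
gen_reflectance <- function(scn, gen) {
  withr::with_seed(scn$rng_seed + 2L, gen_reflectance_impl(scn, gen))
}

gen_reflectance_impl <- function(scn, gen) {
  sites <- gen$sites
  ok <- !gen$truth$expect_validity_fail
  rings <- lapply(sites$geometry_derived[ok], function(g) local_xy(g$xy, scn$origin))
  allxy <- do.call(rbind, rings)
  pad <- 1200
  xmin <- floor(min(allxy[, 1]) - pad); ymin <- floor(min(allxy[, 2]) - pad)
  xmax <- ceiling(max(allxy[, 1]) + pad); ymax <- ceiling(max(allxy[, 2]) + pad)
  res <- scn$reflect_res_m
  nc <- ceiling((xmax - xmin) / res); nr <- ceiling((ymax - ymin) / res)
  traj <- scenario_ndvi(scn)
  rows <- list()
  for (per in PANEL_PERIODS) {
    v_bg <- traj$annulus[[per]]
    ndvi_field <- matrix(v_bg, nr, nc)
    for (ring in rings) {
      cells <- cells_inside(ring, ldis_raster(ndvi_field, xmin, ymin, res, scn$origin))
      ndvi_field[cells] <- traj$site[[per]]
    }
    nir_m <- (1 + ndvi_field) / 2
    red_m <- (1 - ndvi_field) / 2
    cloud_m <- matrix(0, nr, nc)
    if (scn$cloud_rate > 0) {
      cloud_m[stats::runif(nr * nc) < scn$cloud_rate] <- 1
    }
    mk <- function(v) ldis_raster(v, xmin, ymin, res, scn$origin)
    rows[[per]] <- tibble::tibble(
      period = per,
      year = scn$planting_year + PERIOD_OFFSETS[[per]],
      nir = list(mk(nir_m)), red = list(mk(red_m)),
      red_edge = list(mk(red_m)), cloud = list(mk(cloud_m)))
  }
  dplyr::bind_rows(rows)
}

#' Generate a balanced 2x2 difference-in-differences panel
#'
#' Simulates `n_obs` observations (`n_obs / 4` sites, two zones, two
#' periods) from the two-period interaction model with the given cell-mean
#' parameters and iid Gaussian noise. The published regressions are
#' available as named presets via [did_preset()].
#'
#' @param params a [did_preset()]-style list (`intercept`, `beta_g`,
#'   `beta_t`, `beta_gt`, `residual_sd`, `baseline`, `period_after`).
#' @param n_obs total observations; must be divisible by 4 (defaults to
#'   the preset's published n).
#' @param seed integer seed.
#' @return A panel tibble: `site_id`, `zone`, `period`, `year`, `ndvi`,
#'   `n_valid_cells`.
#' @export
gen_did_panel <- function(params = did_preset("table6_col2"),
                          n_obs = params$n_obs, seed = 1L) {
  if (n_obs %% 4 != 0) stop("n_obs must be divisible by 4", call. = FALSE)
  n_sites <- n_obs %/% 4L
  g <- rep(c(0L, 0L, 1L, 1L), n_sites)
  t <- rep(c(0L, 1L, 0L, 1L), n_sites)
  mu <- params$intercept + params$beta_g * g + params$beta_t * t +
    params$beta_gt * g * t
  y <- withr::with_seed(seed, mu + stats::rnorm(n_obs, 0, params$residual_sd))
  tibble::tibble(
    site_id = rep(sprintf("s%07d", seq_len(n_sites)), each = 4L),
    zone = ifelse(g == 1L, "site", "annulus"),
    period = ifelse(t == 1L, params$period_after, params$baseline),
    year = NA_integer_,
    ndvi = y,
    n_valid_cells = 1L)
}
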