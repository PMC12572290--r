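# Overlay metrics: class fractions, road metrics, loss windows, terrain.

test_that("class fractions recover painted checkerboards exactly", {
  vals <- outer(1:50, 1:50, function(r, c) ifelse((r + c) %% 2 == 0, 1, 2))
  r <- ldis_raster(vals, 0, 0, 10, FIX_ORIGIN)
  sq <- local_square(100, 100, 200)  # aligned to an even block of cells
  expect_equal(as.numeric(class_fraction(sq, r, 1)), 0.5, tolerance = 1e-9)
  expect_equal(as.numeric(class_fraction(sq, r, c(1, 2))), 1, tolerance = 1e-9)
  expect_equal(as.numeric(class_fraction(sq, r, integer(0))), 0)
})

test_that("class fractions are additive over disjoint class sets", {
  set.seed(3)
  vals <- matrix(sample(1:4, 40 * 40, replace = TRUE), 40, 40)
  r <- ldis_raster(vals, 0, 0, 10, FIX_ORIGIN)
  tri <- local_poly(cbind(c(30, 370, 180), c(30, 60, 350)))
  f <- vapply(1:4, function(k) as.numeric(class_fraction(tri, r, k)), numeric(1))
  expect_close(sum(f), 1, 1e-9)
  expect_close(as.numeric(class_fraction(tri, r, c(1, 3))), f[1] + f[3], 1e-9)
})

test_that("sites outside or partly outside the raster are flagged", {
  r <- ldis_raster(matrix(1, 10, 10), 0, 0, 10, FIX_ORIGIN)
  far <- local_square(5000, 5000, 100)
  expect_warning(f <- class_fraction(far, r, 1), "does not overlap")
  expect_true(is.na(f))
  straddle <- local_square(50, 50, 100)
  expect_warning(f2 <- class_fraction(straddle, r, 1), "covered")
  expect_equal(as.numeric(f2), 1)
  expect_lt(attr(f2, "covered_frac"), 0.5)
})

test_that("road metrics match the straight-road closed forms", {
  sq <- local_square(0, 0, 1000)  # 1 km^2
  road <- local_line(cbind(c(-500, 1500), c(500, 500)))  # 2 km inside span 1 km
  m <- road_metrics(sq, tibble::tibble(geometry = list(road)))
  expect_close(m$road_length_km, 1, 0.01)
  expect_close(m$road_density_km_per_km2, 1, 0.02)
  expect_close(m$road_cover_fraction, 0.01, 0.001)
  expect_equal(road_metrics(sq, NULL),
               list(road_length_km = 0, road_density_km_per_km2 = 0,
                    road_cover_fraction = 0))
})

test_that("road length is invariant to re-noding the input lines", {
  sq <- local_square(0, 0, 1000)
  whole <- local_line(cbind(c(-200, 1200), c(300, 700)))
  xs <- seq(-200, 1200, length.out = 15)
  ys <- seq(300, 700, length.out = 15)
  parts <- lapply(seq_len(14), function(i)
    local_line(cbind(xs[i:(i + 1)], ys[i:(i + 1)])))
  m1 <- road_metrics(sq, list(whole))
  m2 <- road_metrics(sq, parts)
  expect_close(m1$road_length_km, m2$road_length_km, 1e-6)
})

test_that("loss windows follow the five-year rules and their subset relation", {
  # 30% of the site lost two years before planting
  vals <- matrix(0, 40, 40)
  vals[, 1:12] <- 2016  # planting 2018: loss at planting-2
  r <- ldis_raster(vals, 0, 0, 10, FIX_ORIGIN, year_min = 2001, year_max = 2023)
  sq <- local_square(0, 0, 400)
  lw <- loss_window_fractions(sq, r, 2018L)
  expect_close(lw$loss_frac_pre5, 0.30, 1e-9)
  expect_equal(lw$loss_frac_pre1, 0)
  expect_equal(lw$loss_frac_post5, 0)
  expect_false(lw$post5_truncated)

  none <- ldis_raster(matrix(0, 40, 40), 0, 0, 10, FIX_ORIGIN,
                      year_min = 2001, year_max = 2023)
  lw0 <- loss_window_fractions(sq, none, 2018L)
  expect_equal(unlist(lw0[1:3], use.names = FALSE), c(0, 0, 0))

  # planting in the raster's final year: empty post window, flagged
  lw_end <- loss_window_fractions(sq, r, 2023L)
  expect_true(is.na(lw_end$loss_frac_post5))
  expect_true(lw_end$post5_truncated)

  # pre1 is a subset of pre5 for any loss pattern
  set.seed(9)
  vals2 <- matrix(sample(c(0, 2013:2022), 1600, replace = TRUE), 40, 40)
  r2 <- ldis_raster(vals2, 0, 0, 10, FIX_ORIGIN, year_min = 2001, year_max = 2023)
  lw2 <- loss_window_fractions(sq, r2, 2018L)
  expect_lte(lw2$loss_frac_pre1, lw2$loss_frac_pre5 + 1e-12)
  cells_pre1 <- which(vals2 == 2017)
  cells_pre5 <- which(vals2 %in% 2013:2017)
  cells_post5 <- which(vals2 %in% 2019:2022)
  expect_true(all(cells_pre1 %in% cells_pre5))
  expect_length(intersect(cells_pre1, cells_post5), 0L)

  lw_na <- loss_window_fractions(sq, r, NA)
  expect_true(all(is.na(unlist(lw_na[1:3]))))
})

test_that("terrain statistics recover constant and ramp DEMs", {
  flat <- ldis_raster(matrix(500, 30, 30), 0, 0, 90, FIX_ORIGIN)
  sq <- local_square(450, 450, 900)
  ts <- terrain_stats(sq, flat)
  expect_equal(ts$mean_elevation_m, 500)
  expect_equal(ts$mean_slope_deg, 0)

  ramp <- ldis_raster(outer(1:30, 1:30, function(r, c) 500 + c), 0, 0, 90, FIX_ORIGIN)
  ts2 <- terrain_stats(sq, ramp)
  expect_close(ts2$mean_slope_deg, atan(1 / 90) * 180 / pi, 1e-6)

  tiny <- local_square(400, 400, 20)  # smaller than one 90 m cell
  ts3 <- terrain_stats(tiny, ramp)
  expect_false(is.na(ts3$mean_elevation_m))
})

test_that("zonal means are invariant to raster tiling", {
  set.seed(5)
  vals <- matrix(runif(60 * 60), 60, 60)
  full <- ldis_raster(vals, 0, 0, 10, FIX_ORIGIN)
  left <- ldis_raster(vals[, 1:30], 0, 0, 10, FIX_ORIGIN)
  right <- ldis_raster(vals[, 31:60], 300, 0, 10, FIX_ORIGIN)
  tri <- local_poly(cbind(c(40, 560, 300), c(40, 80, 560)))
  zf <- ldiscore:::zonal_values(tri, full)
  zl <- suppressWarnings(ldiscore:::zonal_values(tri, left))
  zr <- suppressWarnings(ldiscore:::zonal_values(tri, right))
  mean_full <- sum(zf$values * zf$weights) / sum(zf$weights)
  mean_tiled <- (sum(zl$values * zl$weights) + sum(zr$values * zr$weights)) /
    (sum(zl$weights) + sum(zr$weights))
  expect_close(mean_tiled, mean_full, 1e-9)
})

test_that("raster ASCII round-trip preserves grid and metadata", {
  r <- ldis_raster(matrix(c(1, 2, NA, 4), 2, 2), 10, 20, 30, FIX_ORIGIN,
                   year_max = 2023)
  f <- withr::local_tempfile(fileext = ".asc")
  write_raster_asc(r, f)
  back <- read_raster_asc(f)
  expect_equal(back$values, r$values)
  expect_equal(back$res, r$res)
  expect_equal(back$origin, r$origin)
  expect_equal(back$meta$year_max, 2023)
})
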