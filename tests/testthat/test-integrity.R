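# Geometric integrity diagnostics: validity, circularity, admin matching,
# overlap classification, annuli.

test_that("validity distinguishes simple rings from degenerate input", {
  expect_true(validate_geometry(local_square(0, 0, 100)))
  bowtie <- local_poly(cbind(c(0, 100, 0, 100), c(0, 100, 100, 0)))
  expect_false(validate_geometry(bowtie))
  flat <- local_poly(cbind(c(0, 100, 200), c(0, 0, 0)))
  expect_false(validate_geometry(flat))  # shoelace area is exactly 0
})

test_that("circularity matches closed forms for square, rectangle and disc", {
  expect_close(compute_circularity(local_square(0, 0, 400)), pi / 4, 1e-4)
  rect <- local_poly(cbind(c(0, 1000, 1000, 0), c(0, 0, 10, 10)))
  expect_close(compute_circularity(rect), 4 * pi * 10000 / 2020^2, 1e-4)
  disc <- local_poly(ldiscore:::disc_ring(c(0, 0), 300, n = 256L))
  expect_close(compute_circularity(disc), 1, 0.01)
  expect_error(compute_circularity(geo_point(37, -0.5)), "valid polygon")
})

test_that("circularity is invariant under translation, rotation and scaling", {
  base <- cbind(c(0, 300, 350, 100), c(0, 50, 300, 250))
  ref <- compute_circularity(local_poly(base))
  for (k in 1:5) {
    th <- k * 0.7
    rot <- base %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
    moved <- sweep(rot * (0.5 + k / 3), 2, c(1000 * k, -500 * k), "+")
    expect_close(compute_circularity(local_poly(moved)), ref, 1e-6 * ref + 1e-9)
  }
})

test_that("perfect-circle flag applies the configured threshold", {
  cfg <- ldis_config()
  expect_true(flag_perfect_circle(0.99, cfg))
  expect_false(flag_perfect_circle(pi / 4, cfg))
  # a point site's 100 m derived disc always trips the flag
  s <- site_table(list(geo_point(36.8, -1.3)))
  expect_true(flag_perfect_circle(compute_circularity(s$geometry_derived[[1]]), cfg))
})

test_that("admin matching needs mutual >98% overlap and self-matches", {
  adm_ring <- cbind(c(0, 2000, 2000, 0), c(0, 0, 2000, 2000))
  admins <- tibble::tibble(admin_id = c("A1", "A2"), name = c("a", "b"),
                           level = 2L,
                           geometry = list(local_poly(adm_ring),
                                           local_poly(adm_ring + 10000)))
  exact <- match_admin_area(local_poly(adm_ring), admins)
  expect_true(exact$matched); expect_equal(exact$admin_id, "A1")

  half <- local_poly(cbind(c(0, 2000, 2000, 0), c(0, 0, 1000, 1000)))
  expect_false(match_admin_area(half, admins)$matched)

  # concentric shrink to 98.5% of the area: both ratios exceed 0.98
  sh <- sqrt(0.985)
  shrunk <- sweep((adm_ring - 1000) * sh, 2, c(1000, 1000), "+")
  m <- match_admin_area(local_poly(shrunk), admins)
  expect_true(m$matched); expect_equal(m$admin_id, "A1")

  for (i in seq_len(nrow(admins))) {
    expect_true(match_admin_area(admins$geometry[[i]], admins)$matched)
  }
})

test_that("overlap classification separates duplicates, nesting and intersections", {
  sq_big <- local_square(0, 0, 2000)        # 4 km^2
  sq_small <- local_square(500, 500, 1000)  # 1 km^2, fully inside
  dup1 <- local_square(10000, 0, 1000)
  dup2 <- local_square(10001, 0, 1000)      # ~99.9% mutual overlap
  ov1 <- local_square(20000, 0, 1000)
  ov2 <- local_square(20700, 0, 1000)       # 30% overlap
  lone <- local_square(30000, 0, 800)
  sites <- site_table(list(sq_big, sq_small, dup1, dup2, ov1, ov2, lone),
                      ids = c("big", "small", "d1", "d2", "o1", "o2", "lone"))
  rel <- suppressMessages(classify_overlaps(sites))
  rel <- rel[match(sites$site_id, rel$site_id), ]
  expect_equal(rel$nested_in[[2]], "big")
  expect_equal(rel$contains_small_polygon[[1]], "small")
  expect_equal(rel$intersecting_with[[1]], character(0))
  # duplicates: mutual nesting per the published schema
  expect_equal(rel$nested_in[[3]], "d2")
  expect_equal(rel$nested_in[[4]], "d1")
  expect_equal(rel$intersecting_with[[5]], "o2")
  expect_equal(rel$intersecting_with[[6]], "o1")
  expect_equal(rel$nested_in[[5]], character(0))
  expect_length(unlist(rel[rel$site_id == "lone", -1]), 0L)
})

test_that("relations are mutually consistent and never self-referential", {
  scn <- ldis_scenario(n_sites = 40L, rng_seed = 7L)
  gen <- gen_sites(scn)
  rel <- suppressMessages(classify_overlaps(gen$sites))
  for (i in seq_len(nrow(rel))) {
    id <- rel$site_id[i]
    expect_false(id %in% unlist(rel[i, -1]))
    for (j in rel$nested_in[[i]]) {
      expect_true(id %in% rel$contains_small_polygon[[which(rel$site_id == j)]])
    }
    for (j in rel$intersecting_with[[i]]) {
      expect_true(id %in% rel$intersecting_with[[which(rel$site_id == j)]])
    }
  }
})

test_that("grid-indexed classification equals brute force on 200 random sites", {
  set.seed(42)
  n <- 200L
  geoms <- lapply(seq_len(n), function(i) {
    ctr <- c(stats::runif(1, 0, 12000), stats::runif(1, 0, 12000))
    side <- stats::runif(1, 300, 1200)
    local_square(ctr[1], ctr[2], side)
  })
  sites <- site_table(geoms, ids = sprintf("r%03d", seq_len(n)))
  g <- suppressMessages(classify_overlaps(sites, method = "grid"))
  b <- suppressMessages(classify_overlaps(sites, method = "brute"))
  expect_identical(g, b)
})

test_that("annulus areas match closed forms and exclude the site interior", {
  cfg <- ldis_config()
  disc1km <- local_poly(ldiscore:::disc_ring(c(0, 0), 1000, n = 256L))
  ann <- make_annulus(disc1km, cfg)
  expect_close(geo_area_km2(ann), pi * (1.5^2 - 1^2), 0.01 * pi * 1.25)

  pt <- site_table(list(geo_point(37, -0.5)))
  ann_pt <- make_annulus(pt$geometry_derived[[1]], cfg)
  expect_close(geo_area_km2(ann_pt), pi * (0.6^2 - 0.1^2), 0.011)

  # no raster cell contributes to both zones
  r <- ldis_raster(matrix(0, 120, 120), -1500, -1500, 25, FIX_ORIGIN)
  sq <- local_square(-400, -400, 800)
  w_site <- cell_weights(sq, r)
  w_ann <- cell_weights(make_annulus(sq, cfg), r)
  both <- dplyr::inner_join(w_site, w_ann, by = c("row", "col"))
  expect_true(all(both$w.x + both$w.y <= 1 + 1e-9))
  full_site <- both[both$w.x >= 1 - 1e-9, ]
  expect_true(all(full_site$w.y < 1e-9))
})
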