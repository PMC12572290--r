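# Indicator binarization and LDIS aggregation.

flags_row <- function(nested = character(0), inter = character(0),
                      admin = FALSE, circle = FALSE, valid = TRUE) {
  tibble::tibble(site_id = "s", circularity = 0.5,
                 is_perfectly_circular = circle,
                 is_exact_administrative_area = admin,
                 matched_admin_id = NA_character_,
                 geometry_valid = valid, project_geometries_invalid = !valid,
                 nested_in = list(nested), intersecting_with = list(inter),
                 contains_small_polygon = list(character(0)))
}

metrics_row <- function(...) {
  m <- zero_metrics("s")
  over <- list(...)
  for (nm in names(over)) m[[nm]] <- over[[nm]]
  m
}

test_that("threshold strictness matches the published phrasing", {
  cfg <- ldis_config()
  ind <- binarize_indicators(flags_row(), metrics_row(built_fraction = 0.101), cfg)
  expect_equal(unname(ind["built_area_presence"]), "fail")
  ind <- binarize_indicators(flags_row(), metrics_row(built_fraction = 0.10), cfg)
  expect_equal(unname(ind["built_area_presence"]), "pass")
  ind <- binarize_indicators(flags_row(),
                             metrics_row(treecover_at_planting_fraction = 0.20), cfg)
  expect_equal(unname(ind["forest_at_planting_glad"]), "fail")
  ind <- binarize_indicators(flags_row(),
                             metrics_row(road_cover_fraction = 0.100001), cfg)
  expect_equal(unname(ind["road_presence"]), "fail")
})

test_that("permanent water counts toward the configured rule", {
  m <- metrics_row(other_landcover_fraction = 0.12, permanent_water_fraction = 0.1)
  ind <- binarize_indicators(flags_row(), m, ldis_config())
  expect_equal(unname(ind["other_landcover_score"]), "fail")  # 0.22 >= 0.20
  ind2 <- binarize_indicators(flags_row(), m, ldis_config(water_in_landcover = FALSE))
  expect_equal(unname(ind2["other_landcover_score"]), "pass")
  expect_equal(unname(ind2["built_area_presence"]), "pass")  # 0 + 0.1 not > 0.1
})

test_that("missing overlay metrics leave geometry indicators evaluated", {
  ind <- binarize_indicators(flags_row(circle = TRUE), NULL, ldis_config())
  overlay_ind <- c("road_presence", "built_area_presence", "forest_at_planting_glad",
                   "other_landcover_score", "stable_cropland_score")
  expect_true(all(ind[overlay_ind] == "missing"))
  expect_equal(unname(ind["perfect_circle_indicator"]), "fail")
  expect_equal(unname(ind["geometry_validity"]), "pass")
  rec <- ldis_score(ind)
  expect_equal(rec$n_evaluated, 5L)
  expect_equal(rec$completeness, 0.5)
  strict <- ldis_score(ind, strict_missing = TRUE)
  expect_equal(strict$n_evaluated, 10L)
  expect_equal(strict$score, rec$score)
})

test_that("the score counts passes and rejects malformed maps", {
  expect_equal(ldis_score(indicator_map("pass"))$score, 10L)
  one_fail <- indicator_map("pass"); one_fail["nesting_polygon"] <- "fail"
  expect_equal(ldis_score(one_fail)$score, 9L)
  bad <- indicator_map("pass"); names(bad)[1] <- "unknown_indicator"
  expect_error(ldis_score(bad), "canonical keys")
  bad2 <- indicator_map("pass"); bad2[1] <- "maybe"
  expect_error(ldis_score(bad2), "pass/fail/missing")
})

test_that("score is monotone, permutation-invariant and equally weighted", {
  set.seed(11)
  for (rep in seq_len(10000)) {
    map <- stats::setNames(sample(c("pass", "fail", "missing"), 10, replace = TRUE),
                           ldis_indicator_names())
    s <- ldis_score(map)$score
    # permutation invariance
    if (rep <= 50) {
      perm <- sample(map)
      expect_identical(ldis_score(perm)$score, s)
    }
    # single-flip monotonicity + equal weighting
    passing <- which(map == "pass")
    if (length(passing)) {
      flip <- map; flip[passing[1]] <- "fail"
      expect_identical(ldis_score(flip)$score, s - 1L)
    }
  }
})

test_that("cohort summaries reproduce the structural score shares", {
  # every indicator passing: nobody at <= 9
  geoms <- lapply(seq_len(20), function(i) local_square(i * 3000, 0, 500))
  sites <- site_table(geoms)
  flags <- geometry_flags(sites)
  sc <- score_table(sites, flags, zero_metrics(sites$site_id))
  expect_equal(glance(sc)$share_score_le9, 0)

  # point-derived cohort: nobody at 10
  pts <- site_table(lapply(seq_len(20), function(i) {
    ll <- ldiscore:::lonlat_xy(matrix(c(i * 3000, 0), ncol = 2), FIX_ORIGIN)
    geo_point(ll[1], ll[2])
  }))
  scp <- score_table(pts, geometry_flags(pts), zero_metrics(pts$site_id))
  expect_equal(glance(scp)$share_perfect, 0)
  expect_true(all(scp$perfect_circle_indicator == "fail"))

  # 21 of 100 passing everything: 79% at <= 9
  status <- indicator_map("pass")
  sc100 <- purrr::map_dfr(seq_len(100), function(i) {
    m <- status
    if (i > 21) m["intersecting_polygon"] <- "fail"
    ldis_score(m)
  })
  expect_equal(mean(sc100$score <= 9), 0.79)
})

test_that("score tables join by id and report orphans", {
  sites <- site_table(list(local_square(0, 0, 300)))
  flags <- geometry_flags(sites)
  flags$site_id <- "other"
  expect_error(score_table(sites, flags), "without flags")
})
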