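# Geometric integrity diagnostics: validity, circularity, administrative-
# area resemblance, nesting/duplicate/intersection relations, annuli.

#' Validate a geometry
#'
#' A polygon is valid iff its ring is closed, non-self-intersecting and has
#' positive area (checked in a local metric frame). Points are valid;
#' multipolygons are valid iff every part is.
#'
#' @param geom an `ldis_geom`.
#' @return `TRUE` or `FALSE`; degenerate input returns `FALSE`, never errors.
#' @examples
#' validate_geometry(geo_polygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))))   # TRUE
#' validate_geometry(geo_polygon(cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))))   # bow-tie: FALSE
#' @export
validate_geometry <- function(geom) {
  if (is.null(geom)) return(FALSE)
  ok <- tryCatch(switch(geom$type,
    point = TRUE,
    polygon = ring_is_simple(local_xy(geom$xy, geom_anchor(geom))),
    annulus = ring_is_simple(local_xy(geom$xy$outer, geom_anchor(geom))),
    multipolygon = all(vapply(geom$xy, function(r)
      ring_is_simple(local_xy(r, colMeans(r))), logical(1)))),
    error = function(e) FALSE)
  isTRUE(ok)
}

#' Polsby-Popper circularity of a polygon
#'
#' The isoperimetric quotient 4*pi*A/P^2 computed after projection to a
#' local azimuthal-equidistant metric frame; equals 1 for a perfect disc,
#' pi/4 for a square, and decreases toward 0 for elongated shapes.
#'
#' @param geom an `ldis_geom` polygon (or annulus; its outer ring is used).
#' @return A ratio in (0, 1].
#' @examples
#' sq <- geo_polygon(cbind(c(0, 0.01, 0.01, 0), c(0, 0, 0.01, 0.01)))
#' compute_circularity(sq)  # ~ pi/4
#' @export
compute_circularity <- function(geom) {
  if (!validate_geometry(geom) || geom$type == "point") {
    stop("circularity requires a valid polygon", call. = FALSE)
  }
  ring <- geom_local_ring(geom)
  a <- ring_area(ring)
  p <- ring_perimeter(ring)
  min(4 * pi * a / p^2, 1)
}

#' Flag a near-perfect circle
#'
#' @param circ circularity in (0, 1].
#' @param cfg a [ldis_config()]; the flag is `circ >= cfg$circle_frac`.
#' @return Logical.
#' @export
flag_perfect_circle <- function(circ, cfg = ldis_config()) {
  circ >= cfg$circle_frac
}

#' Build the control annulus around a site polygon
#'
#' Buffers the ring outward by `cfg$annulus_width_m` in a local metric frame
#' (edge offsets joined by vertex arcs) and subtracts the original ring,
#' giving the ring-shaped control zone between the site boundary and its
#' outward extension. The result is disjoint from the site interior by
#' construction.
#'
#' @param geom an `ldis_geom` polygon (convex ring or disc).
#' @param cfg a [ldis_config()].
#' @return An `ldis_geom` of type "annulus".
#' @export
make_annulus <- function(geom, cfg = ldis_config()) {
  if (!validate_geometry(geom) || geom$type != "polygon") {
    stop("annulus requires a valid polygon", call. = FALSE)
  }
  origin <- geom_anchor(geom)
  ring <- local_xy(geom$xy, origin)
  outer <- buffer_convex_ring(ring, cfg$annulus_width_m)
  geo_annulus(lonlat_xy(outer, origin), geom$xy)
}

#' Match a site polygon against administrative regions
#'
#' A site is an "exact administrative area" iff some region overlaps it with
#' more than `cfg$admin_overlap_frac` of *both* areas (strict `>`, mutual).
#' When several regions qualify, the one maximizing the smaller of the two
#' overlap ratios wins.
#'
#' @param geom an `ldis_geom` polygon.
#' @param admins admin tibble: `admin_id`, `name`, `level`, `geometry`
#'   (list column of `ldis_geom`).
#' @param cfg a [ldis_config()].
#' @return A list: `matched` (logical), `admin_id` (string or `NA`).
#' @export
match_admin_area <- function(geom, admins, cfg = ldis_config()) {
  stopifnot(nrow(admins) > 0)
  origin <- geom_anchor(geom)
  ring <- local_xy(geom$xy, origin)
  a_site <- ring_area(ring)
  best <- NA_character_; best_score <- -Inf
  gb <- bbox_of(geom$xy)
  for (i in seq_len(nrow(admins))) {
    adm <- admins$geometry[[i]]
    if (!bboxes_overlap(gb, bbox_of(adm$xy), tol = 0.01)) next
    ar <- local_xy(adm$xy, origin)
    inter <- ring_intersection_area(ring, ar)
    if (inter <= 0) next
    r_site <- inter / a_site
    r_adm <- inter / ring_area(ar)
    if (r_site > cfg$admin_overlap_frac && r_adm > cfg$admin_overlap_frac) {
      score <- min(r_site, r_adm)
      if (score > best_score) { best_score <- score; best <- admins$admin_id[i] }
    }
  }
  list(matched = !is.na(best), admin_id = best)
}

# Candidate pairs whose lon/lat bounding boxes overlap. "grid" bins bboxes
# into a coarse regular grid (an STR-style index); "brute" checks all pairs.
candidate_pairs <- function(bboxes, method = c("grid", "brute")) {
  method <- match.arg(method)
  n <- length(bboxes)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  bb <- do.call(rbind, bboxes)
  if (method == "brute") {
    idx <- utils::combn(n, 2)
    keep <- vapply(seq_len(ncol(idx)), function(k)
      bboxes_overlap(bb[idx[1, k], ], bb[idx[2, k], ]), logical(1))
    return(t(idx[, keep, drop = FALSE]))
  }
  cell <- max(stats::median(bb[, 3] - bb[, 1]), stats::median(bb[, 4] - bb[, 2]), 1e-6) * 2
  x0 <- min(bb[, 1]); y0 <- min(bb[, 2])
  pairs <- new.env(parent = emptyenv())
  buckets <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    cx <- floor((bb[i, c(1, 3)] - x0) / cell)
    cy <- floor((bb[i, c(2, 4)] - y0) / cell)
    for (gx in cx[1]:cx[2]) for (gy in cy[1]:cy[2]) {
      key <- paste0(gx, ":", gy)
      prev <- buckets[[key]]
      for (j in prev) {
        if (bboxes_overlap(bb[i, ], bb[j, ])) {
          pairs[[paste0(j, "-", i)]] <- c(j, i)
        }
      }
      buckets[[key]] <- c(prev, i)
    }
  }
  out <- do.call(rbind, as.list(pairs))
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

#' Classify pairwise overlap relations between sites
#'
#' For each pair of sites with a nonzero intersection I (areas measured in a
#' shared local metric frame): *duplicates* if I exceeds
#' `cfg$dup_overlap_frac` of both areas (recorded as mutual nesting, since
#' the published schema has no duplicate column, plus a log line); A is
#' *nested in* B if I exceeds the threshold for A only; otherwise the two
#' sites merely *intersect*. Candidate pairs come from a bounding-box grid
#' index, never an all-pairs scan (a brute-force mode exists for
#' cross-checking). Invalid geometries are skipped.
#'
#' @param sites a site tibble (derived geometries are used).
#' @param cfg a [ldis_config()].
#' @param method "grid" (default) or "brute".
#' @return A tibble: `site_id`, `nested_in`, `intersecting_with`,
#'   `contains_small_polygon` (list columns of site-id character vectors).
#' @export
classify_overlaps <- function(sites, cfg = ldis_config(), method = c("grid", "brute")) {
  method <- match.arg(method)
  n <- nrow(sites)
  ids <- sites$site_id
  geoms <- sites$geometry_derived
  valid <- vapply(geoms, validate_geometry, logical(1))
  nested_in <- contains <- intersecting <- rep(list(character(0)), n)
  usable <- which(valid)
  if (length(usable) >= 2) {
    bboxes <- lapply(geoms, function(g) bbox_of(if (g$type == "polygon") g$xy else do.call(rbind, g$xy)))
    cand <- candidate_pairs(bboxes[usable], method = method)
    n_dup <- 0L
    for (k in seq_len(nrow(cand))) {
      i <- usable[cand[k, 1]]; j <- usable[cand[k, 2]]
      origin <- (geom_anchor(geoms[[i]]) + geom_anchor(geoms[[j]])) / 2
      ri <- local_xy(geoms[[i]]$xy, origin)
      rj <- local_xy(geoms[[j]]$xy, origin)
      inter <- ring_intersection_area(ri, rj)
      ai <- ring_area(ri); aj <- ring_area(rj)
      if (inter / min(ai, aj) < 1e-9) next
      fi <- inter / ai; fj <- inter / aj
      t <- cfg$dup_overlap_frac
      if (fi > t && fj > t) {
        n_dup <- n_dup + 1L
        nested_in[[i]] <- c(nested_in[[i]], ids[j])
        nested_in[[j]] <- c(nested_in[[j]], ids[i])
        contains[[i]] <- c(contains[[i]], ids[j])
        contains[[j]] <- c(contains[[j]], ids[i])
      } else if (fi > t) {
        nested_in[[i]] <- c(nested_in[[i]], ids[j])
        contains[[j]] <- c(contains[[j]], ids[i])
      } else if (fj > t) {
        nested_in[[j]] <- c(nested_in[[j]], ids[i])
        contains[[i]] <- c(contains[[i]], ids[j])
      } else {
        intersecting[[i]] <- c(intersecting[[i]], ids[j])
        intersecting[[j]] <- c(intersecting[[j]], ids[i])
      }
    }
    if (n_dup > 0) message(n_dup, " duplicate pair(s) recorded as mutual nesting")
  }
  tibble::tibble(site_id = ids,
                 nested_in = lapply(nested_in, sort),
                 intersecting_with = lapply(intersecting, sort),
                 contains_small_polygon = lapply(contains, sort))
}

#' Compute all geometric integrity flags for a site table
#'
#' Joins per-site validity, circularity, the perfect-circle flag,
#' administrative-area resemblance, and the pairwise overlap relations into
#' one flags table using the published column names.
#'
#' @param sites a site tibble.
#' @param admins optional admin tibble (see [match_admin_area()]); when
#'   `NULL` the admin flag is `FALSE` for every site.
#' @param cfg a [ldis_config()].
#' @return A tibble: `site_id`, `circularity`, `is_perfectly_circular`,
#'   `is_exact_administrative_area`, `matched_admin_id`,
#'   `project_geometries_invalid`, `geometry_valid`, `nested_in`,
#'   `intersecting_with`, `contains_small_polygon`.
#' @export
geometry_flags <- function(sites, admins = NULL, cfg = ldis_config()) {
  n <- nrow(sites)
  valid <- vapply(sites$geometry_derived, validate_geometry, logical(1))
  circ <- rep(NA_real_, n)
  circ[valid] <- vapply(sites$geometry_derived[valid], compute_circularity, numeric(1))
  admin_hit <- rep(FALSE, n); admin_id <- rep(NA_character_, n)
  if (!is.null(admins) && nrow(admins)) {
    for (i in which(valid)) {
      m <- match_admin_area(sites$geometry_derived[[i]], admins, cfg)
      admin_hit[i] <- m$matched; admin_id[i] <- m$admin_id
    }
  }
  rel <- classify_overlaps(sites, cfg)
  tibble::tibble(site_id = sites$site_id,
                 circularity = circ,
                 is_perfectly_circular = !is.na(circ) & flag_perfect_circle(circ, cfg),
                 is_exact_administrative_area = admin_hit,
                 matched_admin_id = admin_id,
                 geometry_valid = valid,
                 project_geometries_invalid = !valid) |>
    dplyr::left_join(rel, by = "site_id")
}
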