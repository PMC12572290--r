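# Reading, harmonizing and writing planting-site tables.
#
# A site table is a tibble with one row per planting site:
#   site_id, project_id_reported, host_name, url, iso3,
#   geometry_reported / geometry_derived (list columns of ldis_geom),
#   geometry_kind ("point"/"polygon"), planting_date_reported (Date),
#   planting_date_type, planting_year, area_reported_km2, area_derived_km2.
# Unknown input columns are preserved as pass-through attributes.

SITE_META_COLS <- c("site_id", "project_id_reported", "host_name", "url", "iso3",
                    "planting_date_reported", "planting_date_type",
                    "area_reported_km2")

DATE_TYPES <- c("planting", "registration", "intervention_year",
                "crediting_start", "unknown")

#' Read and harmonize a planting-site table
#'
#' Reads a GeoJSON FeatureCollection or a CSV with a WKT geometry column,
#' normalizes area units to km^2, resolves duplicate site ids by
#' deterministic suffixing, parses planting dates (year-only dates resolve
#' to July 1 of that year), and derives metric geometries: point sites are
#' buffered by `cfg$point_buffer_m`, polygon sites keep their reported ring.
#' Rows without any geometry are dropped with a logged count.
#'
#' @param path input file.
#' @param format "geojson" or "csv"; guessed from the extension by default.
#' @param cfg a [ldis_config()].
#' @return A site tibble (see package overview); one row per record.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("site_id,area_reported,geometry",
#'              "s1,250 ha,\"POLYGON ((36 -1, 36.01 -1, 36.01 -0.99, 36 -0.99))\""), f)
#' read_sites(f)$area_reported_km2  # 2.5
#' @export
read_sites <- function(path, format = NULL, cfg = ldis_config()) {
  if (!file.exists(path)) stop("cannot read sites: no such file: ", path, call. = FALSE)
  format <- format %||% if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) "geojson" else "csv"
  raw <- switch(format,
    geojson = read_sites_geojson(path),
    csv = read_sites_csv(path),
    stop("unsupported site format: ", format, call. = FALSE))
  harmonize_sites(raw, cfg)
}

read_sites_geojson <- function(path) {
  gj <- tryCatch(jsonlite::read_json(path),
                 error = function(e) stop("unreadable GeoJSON: ", conditionMessage(e), call. = FALSE))
  feats <- gj$features
  if (is.null(feats)) stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  rows <- purrr::map(feats, function(f) {
    props <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
    tibble::as_tibble(props)
  })
  tab <- dplyr::bind_rows(rows)
  tab$geometry_reported <- purrr::map(feats, function(f) {
    tryCatch(geojson_to_geom(f$geometry), error = function(e) NULL)
  })
  tab
}

read_sites_csv <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                           check.names = FALSE))
  gcol <- intersect(c("geometry", "geometry_wkt", "wkt", "geometry_reported"), names(tab))
  if (!length(gcol)) stop("CSV has no WKT geometry column", call. = FALSE)
  tab$geometry_reported <- purrr::map(tab[[gcol[1]]], function(s) {
    tryCatch(geo_parse_wkt(s), error = function(e) NULL)
  })
  tab[[gcol[1]]] <- NULL
  tab
}

# Parse "250 ha" / "2.5 km2" / bare numbers (assumed km^2) into km^2.
normalize_area_km2 <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(tolower(as.character(x)))
  num <- suppressWarnings(as.numeric(gsub("[^0-9eE+.-]", "", x)))
  unit <- gsub("[0-9eE+., -]", "", x)
  mult <- dplyr::case_when(
    unit %in% c("", "km2", "km²", "sqkm") ~ 1,
    unit %in% c("ha", "hectare", "hectares") ~ 0.01,
    unit %in% c("m2", "m²", "sqm") ~ 1e-6,
    TRUE ~ NA_real_)
  if (any(is.na(mult) & !is.na(num))) {
    warning("unrecognized area units left as NA: ",
            paste(unique(unit[is.na(mult)]), collapse = ", "), call. = FALSE)
  }
  num * mult
}

parse_planting_date <- function(x) {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  full <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[full] <- as.Date(x[full])
  yr <- grepl("^\\d{4}$", x)
  if (any(yr)) {
    out[yr] <- as.Date(paste0(x[yr], "-07-01"))
    message(sum(yr), " year-only planting date(s) resolved to July 1")
  }
  out
}

dedup_site_ids <- function(ids) {
  ids <- as.character(ids)
  dup <- duplicated(ids)
  if (any(dup)) {
    warning(sum(dup), " duplicate site_id(s) suffixed deterministically", call. = FALSE)
    ids <- stats::ave(ids, ids, FUN = function(v) {
      if (length(v) == 1) v else c(v[1], paste0(v[-1], "-", seq_along(v[-1]) + 1L))
    })
  }
  ids
}

harmonize_sites <- function(tab, cfg) {
  n0 <- nrow(tab)
  has_geom <- !purrr::map_lgl(tab$geometry_reported, is.null)
  if (any(!has_geom)) {
    message(sum(!has_geom), " record(s) without geometry excluded")
    tab <- tab[has_geom, , drop = FALSE]
  }
  if (!nrow(tab)) stop("no records with geometry in input", call. = FALSE)

  if (!"site_id" %in% names(tab)) tab$site_id <- sprintf("site%04d", seq_len(nrow(tab)))
  tab$site_id <- dedup_site_ids(tab$site_id)

  # area: accept area_reported_km2 as-is, or area_reported with embedded units
  if ("area_reported_km2" %in% names(tab)) {
    tab$area_reported_km2 <- normalize_area_km2(tab$area_reported_km2)
  } else if ("area_reported" %in% names(tab)) {
    tab$area_reported_km2 <- normalize_area_km2(tab$area_reported)
    tab$area_reported <- NULL
  } else tab$area_reported_km2 <- NA_real_

  if ("planting_date_reported" %in% names(tab)) {
    if (!inherits(tab$planting_date_reported, "Date")) {
      tab$planting_date_reported <- parse_planting_date(tab$planting_date_reported)
    }
  } else tab$planting_date_reported <- as.Date(NA)
  tab$planting_date_type <- if (!"planting_date_type" %in% names(tab)) "unknown" else {
    ifelse(tab$planting_date_type %in% DATE_TYPES, tab$planting_date_type, "unknown")
  }
  tab$planting_year <- as.integer(format(tab$planting_date_reported, "%Y"))

  for (m in c("project_id_reported", "host_name", "url", "iso3")) {
    if (!m %in% names(tab)) tab[[m]] <- NA_character_
  }
  tab$geometry_kind <- ifelse(
    purrr::map_chr(tab$geometry_reported, geom_type) == "point", "point", "polygon")

  tab <- derive_geometries(tab, cfg)
  ord <- c("site_id", "project_id_reported", "host_name", "url", "iso3",
           "geometry_kind", "geometry_reported", "geometry_derived",
           "planting_date_reported", "planting_date_type", "planting_year",
           "area_reported_km2", "area_derived_km2")
  tab <- dplyr::relocate(tab, dplyr::any_of(ord))
  tab
}

#' Derive metric geometries for a site table
#'
#' Points become discs of radius `cfg$point_buffer_m` built in a local
#' azimuthal-equidistant frame centred on the point; polygons and
#' multipolygons pass through unchanged. `area_derived_km2` is recomputed
#' geodesically on the WGS84 ellipsoid. Idempotent on polygon sites.
#'
#' @param sites a site tibble.
#' @param cfg a [ldis_config()].
#' @return `sites` with `geometry_derived` and `area_derived_km2` filled.
#' @export
derive_geometries <- function(sites, cfg = ldis_config()) {
  sites$geometry_derived <- purrr::map(sites$geometry_reported, function(g) {
    if (geom_type(g) == "point") {
      ring <- disc_ring(c(0, 0), cfg$point_buffer_m, n = 64L)
      geo_polygon(lonlat_xy(ring, g$xy))
    } else g
  })
  sites$area_derived_km2 <- purrr::map_dbl(sites$geometry_derived, geo_area_km2)
  sites
}

#' Explode multipolygon sites into single-ring records
#'
#' Each part of a multipolygon becomes its own record with id
#' `"<parent>#k"` (k in drawing order) and the parent id retained in
#' `parent_site_id`. Zero-area sliver parts are dropped with a logged count.
#' Single polygons and points pass through unchanged.
#'
#' @param sites a site tibble.
#' @param cfg a [ldis_config()].
#' @return A site tibble with one simple geometry per row.
#' @export
explode_multipolygons <- function(sites, cfg = ldis_config()) {
  is_multi <- purrr::map_chr(sites$geometry_reported, geom_type) == "multipolygon"
  if (!any(is_multi)) return(sites)
  n_sliver <- 0L
  rows <- purrr::map(seq_len(nrow(sites)), function(i) {
    row <- sites[i, , drop = FALSE]
    if (!is_multi[i]) return(row)
    parts <- row$geometry_reported[[1]]$xy
    areas <- purrr::map_dbl(parts, function(r) geo_area_km2(geo_polygon(r)))
    keep <- areas > 1e-10
    n_sliver <<- n_sliver + sum(!keep)
    parts <- parts[keep]
    if (!length(parts)) return(row[0, , drop = FALSE])
    out <- row[rep(1L, length(parts)), , drop = FALSE]
    out$parent_site_id <- row$site_id
    out$site_id <- paste0(row$site_id, "#", seq_along(parts))
    out$geometry_reported <- purrr::map(parts, geo_polygon)
    out
  })
  out <- dplyr::bind_rows(rows)
  if (n_sliver > 0) message(n_sliver, " zero-area sliver part(s) dropped")
  if (!"parent_site_id" %in% names(out)) out$parent_site_id <- NA_character_
  derive_geometries(out, cfg)
}

#' Write a site table to GeoJSON or CSV (WKT geometry)
#'
#' Round-trips through [read_sites()]: fields and geometry vertices are
#' preserved to ~1e-9 degrees.
#'
#' @param sites a site tibble.
#' @param path output path; extension selects the format unless given.
#' @param format "geojson" or "csv".
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path, format = NULL) {
  format <- format %||% if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) "geojson" else "csv"
  meta <- sites[setdiff(names(sites),
                        c("geometry_reported", "geometry_derived",
                          "planting_year", "area_derived_km2"))]
  meta$planting_date_reported <- as.character(meta$planting_date_reported)
  if (format == "csv") {
    meta$geometry <- purrr::map_chr(sites$geometry_reported, geo_wkt)
    utils::write.csv(meta, path, row.names = FALSE, na = "")
  } else {
    feats <- purrr::map(seq_len(nrow(sites)), function(i) {
      props <- as.list(meta[i, , drop = FALSE])
      props <- props[!vapply(props, function(v) is.na(v) || is.null(v), logical(1))]
      list(type = "Feature", properties = props,
           geometry = geom_to_geojson(sites$geometry_reported[[i]]))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
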