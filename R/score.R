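# The ten binary integrity indicators and the 0-10 Location Data Integrity
# Score (LDIS). Indicator names replicate the published field names.

LDIS_INDICATORS <- c("road_presence", "built_area_presence",
                     "forest_at_planting_glad", "other_landcover_score",
                     "nesting_polygon", "intersecting_polygon",
                     "exact_admin_area", "perfect_circle_indicator",
                     "geometry_validity", "stable_cropland_score")

#' Binarize geometry flags and overlay metrics into the ten indicators
#'
#' Threshold strictness follows the published phrasing exactly: the 10%
#' infrastructure rules are strict (`> 10%` fails), the 20% land-cover
#' rules are inclusive (`>= 20%` fails). Under the default configuration
#' permanent water counts toward the other-land-cover rule. An indicator
#' whose inputs are missing is `"missing"`, not a pass or a fail.
#'
#' @param flags one-row slice (or list) of a [geometry_flags()] table.
#' @param metrics one-row slice (or list) of an [overlay_metrics()] table;
#'   `NULL` marks all overlay indicators missing.
#' @param cfg a [ldis_config()].
#' @return Named character vector over the ten canonical indicators with
#'   values in `{"pass", "fail", "missing"}`.
#' @export
binarize_indicators <- function(flags, metrics = NULL, cfg = ldis_config()) {
  fbin <- function(x, bad) {
    if (is.null(x) || length(x) == 0 || (is.atomic(x) && is.na(x))) return("missing")
    if (isTRUE(bad(x))) "fail" else "pass"
  }
  m <- function(name) if (is.null(metrics)) NULL else metrics[[name]]
  other_lc <- m("other_landcover_fraction")
  water <- m("permanent_water_fraction")
  built <- m("built_fraction")
  if (!is.null(other_lc) && !is.na(other_lc) && cfg$water_in_landcover &&
      !is.null(water) && !is.na(water)) {
    other_lc <- other_lc + water
  }
  if (!is.null(built) && !is.na(built) && !cfg$water_in_landcover &&
      !is.null(water) && !is.na(water)) {
    built <- built + water
  }
  nested <- flags$nested_in
  if (is.list(nested) && length(nested) == 1) nested <- nested[[1]]
  inter <- flags$intersecting_with
  if (is.list(inter) && length(inter) == 1) inter <- inter[[1]]
  c(road_presence = fbin(m("road_cover_fraction"), function(x) x > cfg$infra_cover_frac),
    built_area_presence = fbin(built, function(x) x > cfg$infra_cover_frac),
    forest_at_planting_glad = fbin(m("treecover_at_planting_fraction"),
                                   function(x) x >= cfg$landcover_cover_frac),
    other_landcover_score = fbin(other_lc, function(x) x >= cfg$landcover_cover_frac),
    nesting_polygon = if (is.null(nested)) "missing" else
      if (length(nested) > 0) "fail" else "pass",
    intersecting_polygon = if (is.null(inter)) "missing" else
      if (length(inter) > 0) "fail" else "pass",
    exact_admin_area = fbin(flags$is_exact_administrative_area, isTRUE),
    perfect_circle_indicator = fbin(flags$is_perfectly_circular, isTRUE),
    geometry_validity = fbin(flags$geometry_valid, function(x) !isTRUE(x)),
    stable_cropland_score = fbin(m("stable_cropland_fraction"),
                                 function(x) x >= cfg$landcover_cover_frac))
}

#' Aggregate an indicator map into an LDIS record
#'
#' The score counts passes. By default a missing indicator is neither a
#' pass nor a fail: it is excluded from the score and reflected only in
#' `completeness` (= evaluated indicators / 10). `strict_missing = TRUE`
#' instead treats missing as fail.
#'
#' @param indicators named vector over the ten canonical indicator names
#'   with values in `{"pass", "fail", "missing"}`.
#' @param strict_missing treat missing indicators as failures.
#' @return A one-row tibble: `score`, `n_evaluated`, `completeness`.
#' @examples
#' ind <- stats::setNames(rep("pass", 10), ldiscore::ldis_indicator_names())
#' ldis_score(ind)$score   # 10
#' @export
ldis_score <- function(indicators, strict_missing = FALSE) {
  if (!setequal(names(indicators), LDIS_INDICATORS)) {
    stop("indicator map must have exactly the ten canonical keys; got: ",
         paste(names(indicators), collapse = ", "), call. = FALSE)
  }
  if (!all(indicators %in% c("pass", "fail", "missing"))) {
    stop("indicator values must be pass/fail/missing", call. = FALSE)
  }
  if (strict_missing) indicators[indicators == "missing"] <- "fail"
  n_pass <- sum(indicators == "pass")
  n_eval <- sum(indicators != "missing")
  tibble::tibble(score = n_pass, n_evaluated = n_eval, completeness = n_eval / 10)
}

#' Canonical LDIS indicator names
#' @return Character vector of the ten indicator names in canonical order.
#' @export
ldis_indicator_names <- function() LDIS_INDICATORS

#' Score a full site table
#'
#' Joins flags and metrics by `site_id`, binarizes the ten indicators per
#' site, and aggregates the LDIS. The result carries a distribution summary
#' (share of sites with score <= 9 and the full histogram, split by
#' geometry kind) retrievable with [glance()][generics::glance].
#'
#' @param sites a site tibble.
#' @param flags a [geometry_flags()] tibble.
#' @param metrics an [overlay_metrics()] tibble, or `NULL`.
#' @param cfg a [ldis_config()].
#' @param strict_missing treat missing indicators as failures.
#' @return A tibble of class `ldis_scores`: `site_id`, `geometry_kind`, the
#'   ten indicator columns, `score`, `n_evaluated`, `completeness`.
#' @export
score_table <- function(sites, flags, metrics = NULL, cfg = ldis_config(),
                        strict_missing = FALSE) {
  orphan <- setdiff(sites$site_id, flags$site_id)
  if (length(orphan)) {
    stop("sites without flags: ", paste(utils::head(orphan, 5), collapse = ", "),
         call. = FALSE)
  }
  fl <- flags[match(sites$site_id, flags$site_id), ]
  me <- if (is.null(metrics)) NULL else metrics[match(sites$site_id, metrics$site_id), ]
  n <- nrow(sites)
  na_col <- function(x) if (is.null(x)) rep(NA_real_, n) else x
  vbin <- function(x, fail) {
    out <- rep("missing", n)
    known <- !is.na(x)
    out[known] <- ifelse(fail[known], "fail", "pass")
    out
  }
  other_lc <- na_col(me$other_landcover_fraction)
  water <- na_col(me$permanent_water_fraction)
  built <- na_col(me$built_fraction)
  if (cfg$water_in_landcover) {
    other_lc <- other_lc + ifelse(is.na(water), 0, water)
  } else {
    built <- built + ifelse(is.na(water), 0, water)
  }
  road <- na_col(me$road_cover_fraction)
  tree <- na_col(me$treecover_at_planting_fraction)
  crop <- na_col(me$stable_cropland_fraction)
  nonempty <- function(lst) vapply(lst, function(v) length(v) > 0, logical(1))
  status <- tibble::tibble(
    road_presence = vbin(road, road > cfg$infra_cover_frac),
    built_area_presence = vbin(built, built > cfg$infra_cover_frac),
    forest_at_planting_glad = vbin(tree, tree >= cfg$landcover_cover_frac),
    other_landcover_score = vbin(other_lc, other_lc >= cfg$landcover_cover_frac),
    nesting_polygon = ifelse(nonempty(fl$nested_in), "fail", "pass"),
    intersecting_polygon = ifelse(nonempty(fl$intersecting_with), "fail", "pass"),
    exact_admin_area = ifelse(fl$is_exact_administrative_area, "fail", "pass"),
    perfect_circle_indicator = ifelse(fl$is_perfectly_circular, "fail", "pass"),
    geometry_validity = ifelse(fl$geometry_valid, "pass", "fail"),
    stable_cropland_score = vbin(crop, crop >= cfg$landcover_cover_frac))
  sm <- as.matrix(status)
  if (strict_missing) sm[sm == "missing"] <- "fail"
  rows <- dplyr::bind_cols(
    tibble::tibble(site_id = sites$site_id, geometry_kind = sites$geometry_kind),
    status,
    tibble::tibble(score = rowSums(sm == "pass"),
                   n_evaluated = rowSums(sm != "missing")))
  rows$completeness <- rows$n_evaluated / 10
  class(rows) <- c("ldis_scores", class(rows))
  rows
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' Distribution summary of an LDIS score table
#'
#' @param x an `ldis_scores` tibble.
#' @param ... unused.
#' @return One row per geometry kind: `n_sites`, `share_score_le9`,
#'   `share_perfect`, `mean_score`.
#' @method glance ldis_scores
#' @export
glance.ldis_scores <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$geometry_kind),
                   n_sites = dplyr::n(),
                   share_score_le9 = mean(.data$score <= 9),
                   share_perfect = mean(.data$score == 10),
                   mean_score = mean(.data$score),
                   .groups = "drop")
}

#' Long-format indicator table from an LDIS score table
#'
#' @param x an `ldis_scores` tibble.
#' @param ... unused.
#' @return A tibble: `site_id`, `indicator`, `status`.
#' @method tidy ldis_scores
#' @export
tidy.ldis_scores <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x)[c("site_id", LDIS_INDICATORS)],
                      -"site_id", names_to = "indicator", values_to = "status")
}

#' Histogram of LDIS scores by geometry kind
#'
#' @param object an `ldis_scores` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ldis_scores
#' @export
autoplot.ldis_scores <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$score)) +
    ggplot2::geom_bar(fill = "forestgreen") +
    ggplot2::facet_wrap(~geometry_kind) +
    ggplot2::scale_x_continuous(breaks = 0:10, limits = c(-0.5, 10.5)) +
    ggplot2::labs(x = "Location Data Integrity Score", y = "sites") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
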