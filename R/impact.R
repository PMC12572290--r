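# Planting-impact estimation: balanced panels, bootstrap mean-change CIs,
# the two-period two-zone difference-in-differences regression, and the
# bucket-weighted synthetic control.

#' Restrict an index panel to sites observed in every required period
#'
#' A site is retained iff it has both zones (site and annulus) for every
#' required period, ensuring a balanced panel for the regression.
#'
#' @param panel a [build_panel()] tibble.
#' @param required_periods character vector of period labels.
#' @return The balanced panel; attributes `n_retained` / `n_dropped` count
#'   sites. Errors if nothing survives.
#' @export
balance_panel <- function(panel, required_periods) {
  need <- length(required_periods) * length(unique(panel$zone))
  counts <- panel |>
    dplyr::filter(.data$period %in% required_periods) |>
    dplyr::distinct(.data$site_id, .data$zone, .data$period) |>
    dplyr::count(.data$site_id)
  keep <- counts$site_id[counts$n == need]
  if (!length(keep)) stop("balanced panel is empty for the required periods", call. = FALSE)
  out <- dplyr::filter(panel, .data$site_id %in% keep,
                       .data$period %in% required_periods)
  attr(out, "n_retained") <- length(keep)
  attr(out, "n_dropped") <- nrow(counts) - length(keep)
  out
}

#' Bootstrap confidence interval for the mean index change
#'
#' Mean change of `outcome` between `baseline` and `period` for one zone,
#' with a percentile bootstrap over sites: site ids are resampled with
#' replacement (both observations of a site travel together), `B`
#' replicates, seeded and bit-reproducible.
#'
#' @param panel a [build_panel()] tibble.
#' @param zone "site" or "annulus".
#' @param period comparison period label.
#' @param baseline baseline period label (default "at_planting").
#' @param outcome index column (default "ndvi").
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @return A tibble: `mean_change`, `ci_lo`, `ci_hi`, `n_sites`, `B`.
#' @export
mean_change_ci <- function(panel, zone, period, baseline = "at_planting",
                           outcome = "ndvi", B = 1000, seed = 1L) {
  bal <- balance_panel(panel[panel$zone == zone, ], c(baseline, period))
  wide <- tidyr::pivot_wider(bal[c("site_id", "period", outcome)],
                             names_from = "period",
                             values_from = dplyr::all_of(outcome))
  change <- wide[[period]] - wide[[baseline]]
  n <- length(change)
  if (n < 2) {
    warning("fewer than 2 sites: CI undefined", call. = FALSE)
    return(tibble::tibble(mean_change = mean(change), ci_lo = NA_real_,
                          ci_hi = NA_real_, n_sites = n, B = as.integer(B)))
  }
  if (B == 1) warning("B = 1 gives a degenerate CI", call. = FALSE)
  reps <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) mean(change[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  qs <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, type = 7)
  tibble::tibble(mean_change = mean(change), ci_lo = qs[1], ci_hi = qs[2],
                 n_sites = n, B = as.integer(B))
}

#' Fit the two-period difference-in-differences regression
#'
#' Ordinary least squares on the saturated 2x2 design
#' `Y = intercept + b_g g + b_t t + b_gt (g x t) + e`, where `g` indicates
#' the treatment zone (the planting site, vs its annulus as control) and
#' `t` indicates the comparison period (vs baseline). On this design the
#' OLS coefficients equal the classical cell-mean contrasts and `b_gt` is
#' the DiD estimate. Standard errors are classical homoskedastic OLS SEs;
#' `cluster = "site"` switches to site-clustered (CR0) errors.
#'
#' For the pre-planting model, set `period_after = "at_planting"` and
#' `baseline = "minus1"`: "after" is the planting date itself.
#'
#' @param panel a [build_panel()] tibble.
#' @param period_after comparison ("after") period label.
#' @param baseline baseline ("before") period label.
#' @param outcome index column (default "ndvi").
#' @param treatment_zone,control_zone zone labels.
#' @param cluster `"none"` (default, matching plain OLS reporting) or `"site"`.
#' @return An object of class `ldis_did` with elements `coef`, `se`, `r2`,
#'   `residual_sd`, `n_obs`, `cell_means`, `fit`.
#' @export
fit_did <- function(panel, period_after = "plus1", baseline = "at_planting",
                    outcome = "ndvi", treatment_zone = "site",
                    control_zone = "annulus", cluster = c("none", "site")) {
  cluster <- match.arg(cluster)
  stopifnot(period_after != baseline)
  bal <- balance_panel(panel[panel$zone %in% c(treatment_zone, control_zone), ],
                       c(baseline, period_after))
  df <- tibble::tibble(y = bal[[outcome]],
                       g = as.integer(bal$zone == treatment_zone),
                       t = as.integer(bal$period == period_after),
                       site = bal$site_id)
  cells <- dplyr::count(df, .data$g, .data$t)
  if (nrow(cells) < 4) stop("empty design cell in DiD panel", call. = FALSE)
  fit <- stats::lm(y ~ g * t, data = df)
  sm <- summary(fit)
  co <- stats::coef(sm)
  se <- co[, "Std. Error"]
  if (cluster == "site") {
    X <- stats::model.matrix(fit)
    u <- stats::residuals(fit)
    XtXinv <- sm$cov.unscaled
    scores <- rowsum(X * u, df$site)
    meat <- crossprod(scores)
    se <- sqrt(diag(XtXinv %*% meat %*% XtXinv))
  }
  cm <- tapply(df$y, list(g = df$g, t = df$t), mean)
  structure(list(
    coef = c(intercept = unname(co["(Intercept)", 1]), beta_g = unname(co["g", 1]),
             beta_t = unname(co["t", 1]), beta_gt = unname(co["g:t", 1])),
    se = c(intercept = unname(se[1]), beta_g = unname(se[2]),
           beta_t = unname(se[3]), beta_gt = unname(se[4])),
    r2 = sm$r.squared, residual_sd = sm$sigma, n_obs = nrow(df),
    cell_means = cm, cluster = cluster,
    spec = list(outcome = outcome, period_after = period_after, baseline = baseline),
    fit = fit), class = "ldis_did")
}

#' @export
print.ldis_did <- function(x, ...) {
  cat(sprintf("Difference-in-differences (%s), %s vs %s, n = %d\n",
              x$spec$outcome, x$spec$period_after, x$spec$baseline, x$n_obs))
  print(round(rbind(estimate = x$coef, se = x$se), 4))
  cat(sprintf("R^2 = %.3f, residual SD = %.3f\n", x$r2, x$residual_sd))
  invisible(x)
}

#' @rdname fit_did
#' @param x an `ldis_did` object.
#' @param ... unused.
#' @method tidy ldis_did
#' @export
tidy.ldis_did <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                 std.error = unname(x$se),
                 statistic = unname(x$coef / x$se),
                 p.value = 2 * stats::pnorm(-abs(unname(x$coef / x$se))))
}

#' @rdname fit_did
#' @method glance ldis_did
#' @export
glance.ldis_did <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, sigma = x$residual_sd, nobs = x$n_obs)
}

#' Counterfactual (no-treatment-effect) predictions from a DiD fit
#'
#' Predictions from the fitted model excluding the interaction term; the
#' treated-after counterfactual is `intercept + beta_g + beta_t`, and the
#' observed treated-after cell mean minus it equals `beta_gt`.
#'
#' @param result an `ldis_did` object.
#' @return A tibble with one row per design cell: `g`, `t`, `observed`,
#'   `predicted`, `counterfactual`.
#' @export
counterfactual_series <- function(result) {
  b <- result$coef
  grid <- tidyr::expand_grid(g = 0:1, t = 0:1)
  grid$observed <- result$cell_means[cbind(grid$g + 1L, grid$t + 1L)]
  grid$predicted <- b["intercept"] + b["beta_g"] * grid$g + b["beta_t"] * grid$t +
    b["beta_gt"] * grid$g * grid$t
  grid$counterfactual <- b["intercept"] + b["beta_g"] * grid$g + b["beta_t"] * grid$t
  grid
}

#' Observed vs counterfactual cell means from a DiD fit
#' @param object an `ldis_did` object.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ldis_did
#' @export
autoplot.ldis_did <- function(object, ...) {
  cf <- counterfactual_series(object)
  long <- tidyr::pivot_longer(cf, c("observed", "counterfactual"),
                              names_to = "series", values_to = "value")
  long$group <- ifelse(long$g == 1, "treatment (site)", "control (annulus)")
  long <- long[!(long$series == "counterfactual" & long$g == 0), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$group,
                                     linetype = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = c(0, 1),
                                labels = c(object$spec$baseline,
                                           object$spec$period_after)) +
    ggplot2::labs(x = NULL, y = object$spec$outcome) +
    ggplot2::theme_minimal()
}

#' Bucket-weighted synthetic control
#'
#' Builds equal-probability quantile buckets from the sites' at-planting
#' NDVI distribution, assigns randomly sampled control points to buckets by
#' their own at-planting NDVI, and reports, per period, the weighted mean
#' of the control points' values with the sites' bucket proportions as
#' weights. Empty buckets are re-weighted proportionally with a warning.
#'
#' @param site_ndvi_at_planting numeric vector over sites.
#' @param control_ndvi_at_planting numeric vector over control points.
#' @param control_panel named list (or tibble) mapping each period to the
#'   control points' values in that period (same order/length as
#'   `control_ndvi_at_planting`).
#' @param n_buckets number of quantile buckets (default 10).
#' @return A list of class `ldis_synth`: `bucket_edges`, `bucket_weights`,
#'   `control_means_by_period`.
#' @export
synthetic_control <- function(site_ndvi_at_planting, control_ndvi_at_planting,
                              control_panel, n_buckets = 10) {
  stopifnot(length(site_ndvi_at_planting) > 0, length(control_ndvi_at_planting) > 0)
  probs <- seq(0, 1, length.out = n_buckets + 1L)
  edges <- unique(stats::quantile(site_ndvi_at_planting, probs, names = FALSE, type = 7))
  if (length(edges) < 2) edges <- c(edges, edges + 1e-9)
  # outermost buckets are unbounded: a control point beyond the site range
  # still belongs to the nearest tail bucket
  cut_edges <- c(-Inf, edges[-c(1, length(edges))], Inf)
  site_b <- cut(site_ndvi_at_planting, cut_edges, include.lowest = TRUE, labels = FALSE)
  weights <- tabulate(site_b, nbins = length(edges) - 1L)
  weights <- weights / sum(weights)
  ctl_b <- cut(control_ndvi_at_planting, cut_edges, include.lowest = TRUE, labels = FALSE)
  if (all(is.na(ctl_b))) stop("all control points fall outside the site buckets", call. = FALSE)
  occupied <- sort(unique(ctl_b[!is.na(ctl_b)]))
  if (length(occupied) < length(weights) && any(weights[-occupied] > 0)) {
    warning("empty control bucket(s): weights renormalized over occupied buckets",
            call. = FALSE)
    w2 <- weights; w2[setdiff(seq_along(weights), occupied)] <- 0
    weights <- w2 / sum(w2)
  }
  period_means <- purrr::map_dbl(as.list(control_panel), function(vals) {
    stopifnot(length(vals) == length(control_ndvi_at_planting))
    by_bucket <- tapply(vals, ctl_b, mean, na.rm = TRUE)
    sum(weights[as.integer(names(by_bucket))] * by_bucket)
  })
  structure(list(bucket_edges = edges, bucket_weights = weights,
                 control_means_by_period = period_means),
            class = "ldis_synth")
}

#' @export
print.ldis_synth <- function(x, ...) {
  cat(sprintf("Synthetic control: %d buckets\n", length(x$bucket_weights)))
  print(round(x$control_means_by_period, 4))
  invisible(x)
}
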