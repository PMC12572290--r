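# Impact analysis: balancing, bootstrap CIs, DiD regression, synthetic
# control.

toy_panel <- function(values_by_site, periods = c("at_planting", "plus1")) {
  rows <- list()
  for (s in names(values_by_site)) {
    v <- values_by_site[[s]]
    for (z in names(v)) for (p in names(v[[z]])) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        site_id = s, zone = z, period = p, year = NA_integer_,
        ndvi = v[[z]][[p]], ndre = NA_real_, savi = NA_real_, n_valid_cells = 1L)
    }
  }
  dplyr::bind_rows(rows)
}

test_that("balancing drops sites missing any required period", {
  full <- list(site = c(at_planting = 0.2, plus1 = 0.3, plus2 = 0.35),
               annulus = c(at_planting = 0.25, plus1 = 0.28, plus2 = 0.3))
  partial <- list(site = c(at_planting = 0.2, plus1 = 0.3),
                  annulus = c(at_planting = 0.25, plus1 = 0.28))
  pan <- toy_panel(list(a = full, b = partial, c = full, d = full, e = partial))
  bal <- balance_panel(pan, c("at_planting", "plus1", "plus2"))
  expect_setequal(unique(bal$site_id), c("a", "c", "d"))
  expect_equal(nrow(bal), 3 * 3 * 2)
  expect_equal(attr(bal, "n_dropped"), 2L)

  bal2 <- balance_panel(pan, c("at_planting", "plus1"))
  expect_equal(nrow(bal2), nrow(pan[pan$period != "plus2", ]))
  expect_error(balance_panel(pan, "plus5"), "empty")
})

test_that("bootstrap CI degenerates correctly and is bit-reproducible", {
  same <- lapply(1:5, function(i)
    list(site = c(at_planting = 0.20, plus1 = 0.25)))
  names(same) <- paste0("s", 1:5)
  pan <- toy_panel(same)
  ci <- mean_change_ci(pan, "site", "plus1", B = 100, seed = 4)
  expect_equal(ci$mean_change, 0.05)
  expect_equal(ci$ci_lo, 0.05)
  expect_equal(ci$ci_hi, 0.05)
  expect_warning(mean_change_ci(pan, "site", "plus1", B = 1, seed = 4), "degenerate")

  set.seed(99)
  vals <- lapply(1:30, function(i)
    list(site = c(at_planting = 0.2, plus1 = 0.2 + rnorm(1, 0.05, 0.01))))
  names(vals) <- paste0("r", 1:30)
  pan2 <- toy_panel(vals)
  a <- mean_change_ci(pan2, "site", "plus1", B = 500, seed = 7)
  b <- mean_change_ci(pan2, "site", "plus1", B = 500, seed = 7)
  expect_identical(a, b)
})

test_that("bootstrap CI covers the true mean change at the nominal rate", {
  n <- 120; B <- 200; hits <- 0; reps <- 60
  for (k in seq_len(reps)) {
    set.seed(1000 + k)
    vals <- lapply(seq_len(n), function(i)
      list(site = c(at_planting = 0, plus1 = rnorm(1, 0.05, 0.01))))
    names(vals) <- sprintf("s%03d", seq_len(n))
    ci <- mean_change_ci(toy_panel(vals), "site", "plus1", B = B, seed = k)
    hits <- hits + (ci$ci_lo <= 0.05 && 0.05 <= ci$ci_hi)
  }
  expect_gte(hits / reps, 0.85)  # 95% nominal, binomial noise at 60 reps
})

test_that("noiseless published cell means are recovered exactly", {
  cells <- list(cb = 0.265, ca = 0.313, tb = 0.175, ta = 0.271)
  vals <- lapply(1:6, function(i) list(
    annulus = c(at_planting = cells$cb, plus1 = cells$ca),
    site = c(at_planting = cells$tb, plus1 = cells$ta)))
  names(vals) <- paste0("s", 1:6)
  f <- suppressWarnings(fit_did(toy_panel(vals), period_after = "plus1"))
  expect_equal(unname(f$coef["intercept"]), 0.265, tolerance = 1e-12)
  expect_equal(unname(f$coef["beta_g"]), -0.090, tolerance = 1e-12)
  expect_equal(unname(f$coef["beta_t"]), 0.048, tolerance = 1e-12)
  expect_equal(unname(f$coef["beta_gt"]), 0.048, tolerance = 1e-12)
  expect_equal(f$r2, 1)
  expect_equal(f$n_obs, 24L)

  cf <- counterfactual_series(f)
  treat_after <- cf[cf$g == 1 & cf$t == 1, ]
  expect_equal(treat_after$counterfactual, 0.265 - 0.090 + 0.048, tolerance = 1e-12)
  expect_equal(treat_after$observed - treat_after$counterfactual,
               unname(f$coef["beta_gt"]), tolerance = 1e-12)
})

test_that("OLS equals cell-mean contrasts and ignores row order and ids", {
  pan <- gen_did_panel(did_preset("table6_col2"), n_obs = 2000, seed = 5)
  f <- fit_did(pan, period_after = "plus1")
  cm <- f$cell_means
  expect_equal(unname(f$coef["intercept"]), cm["0", "0"], tolerance = 1e-12)
  expect_equal(unname(f$coef["beta_g"]), cm["1", "0"] - cm["0", "0"], tolerance = 1e-12)
  expect_equal(unname(f$coef["beta_t"]), cm["0", "1"] - cm["0", "0"], tolerance = 1e-12)
  expect_equal(unname(f$coef["beta_gt"]),
               (cm["1", "1"] - cm["1", "0"]) - (cm["0", "1"] - cm["0", "0"]),
               tolerance = 1e-12)

  shuf <- pan[sample.int(nrow(pan)), ]
  shuf$site_id <- paste0("relabel-", shuf$site_id)
  f2 <- fit_did(shuf, period_after = "plus1")
  expect_equal(f2$coef, f$coef, tolerance = 1e-12)
  expect_equal(f2$r2, f$r2, tolerance = 1e-12)
})

test_that("null interaction stays within three standard errors", {
  null_pre <- list(intercept = 0.3, beta_g = -0.05, beta_t = 0.04, beta_gt = 0,
                   residual_sd = 0.15, baseline = "at_planting",
                   period_after = "plus1")
  inside <- 0
  for (k in 1:100) {
    f <- fit_did(gen_did_panel(null_pre, n_obs = 800, seed = k),
                 period_after = "plus1")
    inside <- inside + (abs(f$coef["beta_gt"]) < 3 * f$se["beta_gt"])
  }
  expect_gte(inside, 99)
})

test_that("coefficient estimates are unbiased over repeated simulation", {
  pre <- list(intercept = 0.25, beta_g = -0.08, beta_t = 0.05, beta_gt = 0.03,
              residual_sd = 0.18, baseline = "at_planting", period_after = "plus1")
  est <- t(vapply(1:100, function(k) {
    fit_did(gen_did_panel(pre, n_obs = 400, seed = 5000 + k),
            period_after = "plus1")$coef
  }, numeric(4)))
  truth <- c(pre$intercept, pre$beta_g, pre$beta_t, pre$beta_gt)
  mc_se <- apply(est, 2, stats::sd) / sqrt(nrow(est))
  expect_true(all(abs(colMeans(est) - truth) < 2 * mc_se + 1e-8))
})

test_that("fitted R2 matches the closed form var(m)/(var(m)+sigma^2) at scale", {
  pre <- did_preset("table6_col4")
  f <- fit_did(gen_did_panel(pre, seed = 31), period_after = pre$period_after,
               baseline = pre$baseline)
  m <- c(pre$intercept, pre$intercept + pre$beta_t,
         pre$intercept + pre$beta_g,
         pre$intercept + pre$beta_g + pre$beta_t + pre$beta_gt)
  vm <- mean((m - mean(m))^2)
  closed <- vm / (vm + pre$residual_sd^2)
  expect_close(f$r2, closed, 0.002)
  expect_close(closed, pre$r2, 0.002)  # internal consistency of the preset
})

test_that("tidy and glance expose broom-style summaries", {
  f <- fit_did(gen_did_panel(did_preset("table6_col2"), n_obs = 400, seed = 2),
               period_after = "plus1")
  td <- tidy(f)
  expect_equal(td$term, c("intercept", "beta_g", "beta_t", "beta_gt"))
  expect_true(all(td$std.error > 0))
  gl <- glance(f)
  expect_equal(gl$nobs, 400L)
  expect_true(gl$r.squared >= 0 && gl$r.squared <= 1)
})

test_that("synthetic control degenerates to the plain mean with one bucket", {
  set.seed(8)
  site_v <- rnorm(400, 0.32, 0.06)
  ctl_v <- rnorm(3000, 0.31, 0.08)
  panel <- list(at_planting = ctl_v, plus1 = ctl_v + 0.01)
  one <- synthetic_control(site_v, ctl_v, panel, n_buckets = 1)
  expect_close(one$control_means_by_period[["at_planting"]], mean(ctl_v), 1e-9)
  expect_close(sum(one$bucket_weights), 1, 1e-9)

  ten <- synthetic_control(site_v, ctl_v, panel, n_buckets = 10)
  expect_close(sum(ten$bucket_weights), 1, 1e-9)
  expect_true(all(diff(ten$bucket_edges) > 0))
  expect_close(ten$control_means_by_period[["plus1"]] -
                 ten$control_means_by_period[["at_planting"]], 0.01, 1e-9)
})

test_that("matching distributions give a weighted mean near the plain mean", {
  set.seed(12)
  pop <- rnorm(5000, 0.35, 0.05)
  site_v <- pop[1:2000]
  ctl_v <- pop[2001:5000]
  res <- synthetic_control(site_v, ctl_v, list(at_planting = ctl_v), n_buckets = 10)
  expect_close(res$control_means_by_period[["at_planting"]], mean(ctl_v), 0.005)
})
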