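test_that("variance partition resolves degenerate and shifted structures", {
  hier <- toy_hier(lakes_per_region = 3, strata = 2, plots = 2)
  set.seed(1)
  # variation only between the two regions (plus hair-thin noise so the
  # REML fit is non-singular): region takes essentially all the variance
  region_eff <- c(R1 = -3, R2 = 3)
  tbl <- tibble::tibble(
    plot = rep(hier$plot, each = 2),
    ses = rep(region_eff[hier$region], each = 2) + rnorm(2 * nrow(hier), 0, 0.01)
  )
  vc <- variance_partition(tbl, hier)
  expect_equal(sum(vc$share_pct), 100, tolerance = 1e-6)
  expect_gt(vc$share_pct[vc$level == "region"], 99)
  expect_true(all(vc$share_pct >= 0))

  # shares are invariant to adding a constant to every SES value
  vc2 <- variance_partition(dplyr::mutate(tbl, ses = ses + 100), hier)
  expect_equal(vc$share_pct, vc2$share_pct, tolerance = 1e-4)

  # residual-only input puts everything within plot
  st <- simulate_ses_table(c(region = 0, lake = 0, depth = 0, plot = 0,
                             residual = 1), hier, n_per_plot = 4, seed = 3)
  vc3 <- variance_partition(st, hier)
  expect_gt(vc3$share_pct[vc3$level == "within_plot"], 90)
})

test_that("environment PCA matches an independent eigendecomposition", {
  set.seed(5)
  env <- tibble::tibble(
    lake = sprintf("L%02d", 1:24),
    secchi_depth = rlnorm(24, 2, 0.4),
    total_n = rlnorm(24, 0, 0.3),
    total_p = rlnorm(24, -2.5, 0.3),
    chlorophyll_a = rlnorm(24, 2, 0.5),
    ph = rlnorm(24, log(8), 0.05),
    temperature = rlnorm(24, log(18), 0.1)
  )
  pca <- pca_environment(env)
  # oracle: eigendecomposition of the correlation matrix of the logs
  R <- cor(log(as.matrix(env[-1])))
  ev <- eigen(R, symmetric = TRUE)
  expect_equal(pca$explained, ev$values / sum(ev$values), tolerance = 1e-10)
  expect_equal(abs(unname(pca$loadings)), abs(unname(ev$vectors)),
               tolerance = 1e-8)
  # loadings are orthonormal; explained fractions non-increasing, sum 1
  expect_equal(crossprod(pca$loadings), diag(6), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(pca$explained) <= 1e-12))
  expect_equal(sum(pca$explained), 1)
  expect_gte(pca$explained[1], 1 / 6)
  # axis 1 oriented so clearer water scores higher
  expect_gt(pca$loadings["secchi_depth", 1], 0)
  # reconstruction from all axes reproduces the standardized matrix
  z <- scale(log(as.matrix(env[-1])))
  recon <- pca$prcomp$x %*% t(pca$prcomp$rotation)
  expect_equal(unname(recon), unname(z), tolerance = 1e-8, ignore_attr = TRUE)

  # two perfectly correlated variables -> axis 1 explains everything
  env2 <- tibble::tibble(lake = c("a", "b", "c", "d"),
                         x = c(1, 2, 3, 4), y = c(2, 4, 6, 8))
  expect_equal(pca_environment(env2, log_transform = FALSE)$explained[1], 1)

  env3 <- dplyr::mutate(env, ph = 8)
  expect_error(pca_environment(env3), "constant")
})

test_that("equal-width binning reproduces the printed transparency levels", {
  b <- bin_gradient(c(0, 2.5, 5), 5)
  expect_equal(b$breaks, 0:5)
  expect_equal(bin_gradient(c(1, 3), 1)$breaks, c(1, 3))
  # the published five-level split of log transparency in [1.47, 2.95]
  b2 <- bin_gradient(c(1.47, 2.95), 5)
  expect_equal(b2$breaks_display[3], 2.06)
  # the maximum falls in the last level; assignment uses unrounded breaks
  b3 <- bin_gradient(c(1.47, 2.0, 2.95), 5)
  expect_equal(b3$levels, c(1L, 2L, 5L))
  expect_error(bin_gradient(c(2, 2), 5), "degenerate")
})

test_that("gradient_trend recovers slopes and handles degenerate input", {
  hier <- toy_hier(lakes_per_region = 4, strata = 4, plots = 3)
  st <- simulate_ses_table(c(region = 0, lake = 0.2, depth = 0, plot = 0,
                             residual = 0.4), hier, n_per_plot = 1, seed = 11,
                           depth_slope = -0.5)
  df <- dplyr::left_join(st, hier[, c("plot", "lake")], by = "plot")
  fit <- gradient_trend(df, water_depth_m, lake)
  expect_equal(fit$method, "lmm")
  expect_lt(abs(fit$slope - (-0.5)), 3 * fit$se)
  expect_equal(fit$direction, "more clustered")

  # constant SES: slope exactly 0, reported as no trend
  dfc <- dplyr::mutate(df, ses = 1.3)
  fitc <- gradient_trend(dfc, water_depth_m, lake)
  expect_equal(fitc$slope, 0)
  expect_equal(fitc$p_value, 1)
  expect_equal(fitc$direction, "none")

  # fewer than two groups falls back to OLS with a warning
  df1 <- df[df$plot %in% hier$plot[hier$lake == hier$lake[1]], ]
  expect_warning(fit1 <- gradient_trend(df1, water_depth_m, lake), "least squares")
  expect_equal(fit1$method, "ols")

  # two-level factor gradient reduces to a group contrast
  dff <- dplyr::left_join(st, hier[, c("plot", "region")], by = "plot") |>
    dplyr::mutate(band = ifelse(region == "R1", "low", "high"),
                  ses = ses + ifelse(region == "R1", 0, -2))
  fitf <- gradient_trend(dff, band)
  expect_equal(fitf$method, "ols")
  expect_lt(fitf$p_value, 0.05)
})

test_that("scale_gradient_trends wires gradients and grouping per scale", {
  scen <- scenario(seed = 31, lakes_per_region = 3, strata_per_lake = 3,
                   plots_per_stratum = 3, pool_size = 20, lambda = 2)
  tr <- generate_traits(scen)
  sv <- generate_survey(scen, tr)
  dend <- build_dendrogram(gower_distance(tr))
  st <- ses_dispersion(sv$community, sv$hier, list(multi_trait = dend),
                       scales = c("depth", "lake"), metrics = c("PW", "Dpw"),
                       n_iter = 99, seed = 8)
  td <- scale_gradient_trends(st, sv$hier, sv$env, scale = "depth")
  expect_setequal(td$metric, c("PW", "Dpw"))
  expect_true(all(td$method %in% c("lmm", "ols", "degenerate")))
  tl <- scale_gradient_trends(st, sv$hier, sv$env, scale = "lake")
  expect_equal(unique(tl$scale), "lake")
  tr2 <- scale_gradient_trends(st, sv$hier, sv$env, scale = "region")
  expect_true(all(tr2$method %in% c("ols", "degenerate", "failed")))
})
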