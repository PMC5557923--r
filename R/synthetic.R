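#' Define a synthetic lake-survey scenario
#'
#' Bundles every parameter of the synthetic data generator: the nested
#' survey design (regions / lakes / 0.5 m depth strata / plots), the species
#' pool and its trait distributions, the environmental-filtering strength
#' and the abundance model. The defaults emulate a two-region survey of 24
#' lakes and 1008 plots with a 50-species macrophyte pool and plot richness
#' constrained to 1-18 species.
#'
#' `lambda` controls deterministic environmental filtering: the occurrence
#' weight of species `i` at a site with trait-axis optimum `opt` is
#' proportional to `exp(-(lambda/K) * sum_k (z_ik - opt)^2)` over the `K`
#' standardized trait axes. `lambda = 0` is the neutral scenario
#' (occurrence independent of traits); larger values cluster co-occurring
#' species in trait space. A named vector gives per-trait strengths.
#'
#' @param seed Integer RNG seed (mandatory).
#' @param n_regions,lakes_per_region,strata_per_lake,plots_per_stratum
#'   Survey design counts (defaults 2, 12, 6, 7: 1008 plots).
#' @param pool_size Species-pool size (default 50).
#' @param fraction_annual Fraction of annual species (default 0.3).
#' @param sla_ldmc_cor Correlation of log SLA with log LDMC (default -0.6,
#'   the leaf-economics trade-off).
#' @param lambda Environmental-filtering strength (scalar or named per-trait
#'   vector; default 0 = neutral).
#' @param target_richness Expected plot richness before the 1-18 constraint
#'   (default 5).
#' @param richness_range Allowed per-plot richness (default `c(1, 18)`).
#' @param abund_sdlog Log-SD of the lognormal abundance lottery (default 1).
#' @param gradient_weights Weights of depth, transparency and elevation in
#'   the site optimum (default `c(depth = 0.5, transparency = 0.35,
#'   elevation = 0.35)`).
#' @param max_retries Rejection-sampling cap for the richness constraint.
#' @return An `fd_scenario` list.
#' @export
scenario <- function(seed,
                     n_regions = 2, lakes_per_region = 12,
                     strata_per_lake = 6, plots_per_stratum = 7,
                     pool_size = 50,
                     fraction_annual = 0.3, sla_ldmc_cor = -0.6,
                     lambda = 0, target_richness = 5,
                     richness_range = c(1, min(18, pool_size)),
                     abund_sdlog = 1,
                     gradient_weights = c(depth = 0.5, transparency = 0.35,
                                          elevation = 0.35),
                     max_retries = 100) {
  if (missing(seed)) stop("scenario seed is required", call. = FALSE)
  stopifnot(n_regions >= 1, lakes_per_region >= 1, strata_per_lake >= 1,
            plots_per_stratum >= 1, pool_size >= 2,
            all(lambda >= 0), target_richness >= 1,
            richness_range[1] >= 1, pool_size >= richness_range[2])
  structure(
    list(seed = as.integer(seed), n_regions = n_regions,
         lakes_per_region = lakes_per_region,
         strata_per_lake = strata_per_lake,
         plots_per_stratum = plots_per_stratum, pool_size = pool_size,
         fraction_annual = fraction_annual, sla_ldmc_cor = sla_ldmc_cor,
         lambda = lambda, target_richness = target_richness,
         richness_range = richness_range, abund_sdlog = abund_sdlog,
         gradient_weights = gradient_weights, max_retries = max_retries),
    class = "fd_scenario"
  )
}

#' Generate a synthetic species-pool trait table
#'
#' Draws the five macrophyte traits: life history (annual/perennial),
#' shoot height (cm, lognormal), specific leaf area and leaf dry mass
#' content (lognormal, negatively correlated on the log scale) and
#' flowering duration (integer months in 1-12).
#'
#' @param scen An `fd_scenario`.
#' @return Trait tibble with a `trait_types` attribute (see
#'   [validate_trait_table()]).
#' @export
generate_traits <- function(scen) {
  stopifnot(inherits(scen, "fd_scenario"))
  set.seed(scen$seed)
  n <- scen$pool_size
  rho <- scen$sla_ldmc_cor
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  tr <- tibble::tibble(
    species = sprintf("sp%02d", seq_len(n)),
    life_history = sample(c("annual", "perennial"), n, replace = TRUE,
                          prob = c(scen$fraction_annual,
                                   1 - scen$fraction_annual)),
    shoot_height = stats::rlnorm(n, meanlog = log(60), sdlog = 0.7),
    specific_leaf_area = exp(log(20) + 0.4 * z1),
    leaf_dry_mass_content = exp(log(0.15) + 0.3 * z2),
    flowering_duration = 1L + stats::rbinom(n, 11L, 0.3)
  )
  attr(tr, "trait_types") <- c(
    life_history = "categorical", shoot_height = "continuous",
    specific_leaf_area = "continuous", leaf_dry_mass_content = "continuous",
    flowering_duration = "continuous"
  )
  attr(tr, "trait_units") <- c(
    life_history = "annual/perennial", shoot_height = "cm",
    specific_leaf_area = "mm2/mg", leaf_dry_mass_content = "g/g",
    flowering_duration = "months"
  )
  tr
}

# standardized trait axes (categorical -> 0/1 indicator before scaling)
trait_axes <- function(traits) {
  types <- attr(traits, "trait_types")
  cols <- lapply(names(types), function(tr) {
    x <- traits[[tr]]
    if (types[[tr]] == "categorical") x <- as.numeric(factor(x)) - 1
    if (stats::sd(x) == 0) rep(0, length(x)) else as.numeric(scale(x))
  })
  z <- do.call(cbind, cols)
  colnames(z) <- names(types)
  z
}

#' Generate a synthetic survey: hierarchy, lake environments and communities
#'
#' Builds the nested spatial design (plots in 0.5 m depth strata in lakes in
#' two regions, one at 16.3 m and one at 1967.4 m elevation), draws per-lake
#' water-quality records organised around a latent trophic axis (clear,
#' nutrient-poor lakes have high Secchi depth and low N, P and
#' chlorophyll-a), and assembles plot communities. Species occurrence
#' weights combine a trait-independent base occupancy with the
#' environmental-filtering kernel of the scenario (see [scenario()]);
#' weights are rescaled so the expected richness matches
#' `target_richness`, occurrences are Bernoulli draws constrained to the
#' scenario richness range by rejection sampling, and abundances are a
#' lognormal lottery conditional on occurrence.
#'
#' @param scen An `fd_scenario`.
#' @param traits Trait table from [generate_traits()] (regenerated from the
#'   scenario if omitted).
#' @return List with `community` (plots x species abundance matrix), `hier`
#'   (spatial hierarchy tibble), `env` (per-lake environment tibble) and
#'   `ground_truth` (the scenario plus the per-site optima).
#' @export
generate_survey <- function(scen, traits = generate_traits(scen)) {
  stopifnot(inherits(scen, "fd_scenario"))
  set.seed(scen$seed + 1L)

  regions <- tibble::tibble(
    region = sprintf("R%d", seq_len(scen$n_regions)),
    elevation_m = if (scen$n_regions == 2) c(16.3, 1967.4)
                  else round(stats::runif(scen$n_regions, 10, 2000), 1)
  )
  lakes <- tibble::tibble(
    lake = sprintf("L%02d", seq_len(scen$n_regions * scen$lakes_per_region)),
    region = rep(regions$region, each = scen$lakes_per_region)
  )
  hier <- tidyr::crossing(
    lakes,
    stratum_i = seq_len(scen$strata_per_lake),
    plot_i = seq_len(scen$plots_per_stratum)
  ) |>
    dplyr::mutate(
      water_depth_m = 0.5 * .data$stratum_i,
      depth_stratum = sprintf("%s_d%02d", .data$lake, .data$stratum_i),
      plot = sprintf("P%04d", dplyr::row_number())
    ) |>
    dplyr::left_join(regions, by = "region") |>
    dplyr::select("plot", "depth_stratum", "water_depth_m", "lake", "region",
                  "elevation_m")

  # latent trophic axis per lake: clear water <-> eutrophic
  nl <- nrow(lakes)
  u <- stats::rnorm(nl)
  env <- tibble::tibble(
    lake = lakes$lake,
    secchi_depth = exp(2.2 + 0.35 * u + stats::rnorm(nl, 0, 0.05)),
    total_n = exp(0.2 - 0.5 * u + stats::rnorm(nl, 0, 0.15)),
    total_p = exp(-2.5 - 0.6 * u + stats::rnorm(nl, 0, 0.15)),
    chlorophyll_a = exp(2.0 - 0.7 * u + stats::rnorm(nl, 0, 0.2)),
    ph = exp(log(8) + stats::rnorm(nl, 0, 0.03)),
    temperature = exp(log(18) + stats::rnorm(nl, 0, 0.08))
  )

  # site optimum on the standardized trait axes: weighted combination of the
  # three scale-specific gradients, standardized across sites
  zstd <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else as.numeric(scale(x))
  }
  gw <- scen$gradient_weights
  site <- hier |>
    dplyr::left_join(env[, c("lake", "secchi_depth")], by = "lake") |>
    dplyr::mutate(
      opt = (gw[["depth"]] * zstd(.data$water_depth_m) +
             gw[["transparency"]] * zstd(log(.data$secchi_depth)) +
             gw[["elevation"]] * zstd(.data$elevation_m)) /
            sqrt(sum(gw^2))
    )

  z <- trait_axes(traits)
  K <- ncol(z)
  lam <- scen$lambda
  if (length(lam) == 1L) lam <- stats::setNames(rep(lam, K), colnames(z))
  lam <- lam[colnames(z)]

  n_sp <- scen$pool_size
  base_occ <- stats::rbeta(n_sp, 1.2, 12)
  rmin <- scen$richness_range[1]; rmax <- scen$richness_range[2]

  comm <- matrix(0, nrow(hier), n_sp,
                 dimnames = list(hier$plot, traits$species))
  for (s in seq_len(nrow(site))) {
    pen <- colSums(lam * t(z - site$opt[s])^2) / K
    wgt <- base_occ * exp(-pen)
    p <- pmin(wgt * scen$target_richness / sum(wgt), 0.98)
    occ <- NULL
    for (try_i in seq_len(scen$max_retries)) {
      draw <- stats::runif(n_sp) < p
      if (sum(draw) >= rmin && sum(draw) <= rmax) { occ <- draw; break }
    }
    if (is.null(occ)) {
      # retry cap hit: force the richest feasible community deterministically
      k <- max(rmin, min(rmax, round(sum(p))))
      occ <- logical(n_sp)
      occ[order(p, decreasing = TRUE)[seq_len(k)]] <- TRUE
    }
    comm[s, occ] <- stats::rlnorm(sum(occ), meanlog = 0,
                                  sdlog = scen$abund_sdlog)
  }

  list(
    community = comm,
    hier = hier,
    env = env,
    ground_truth = list(scenario = scen, site_optimum = site$opt,
                        base_occupancy = base_occ)
  )
}

#' Simulate an SES table with a known nested variance structure
#'
#' Draws SES values directly as sums of independent normal effects at the
#' region, lake, depth-stratum and plot levels plus a within-plot residual,
#' with `n_per_plot` replicate values per plot. Used as ground truth for
#' variance-component recovery; `depth_slope` optionally adds a fixed linear
#' effect of stratum water depth for trend-recovery tests.
#'
#' @param variances Named non-negative variances: `region`, `lake`, `depth`,
#'   `plot`, `residual`.
#' @param hier Spatial hierarchy.
#' @param n_per_plot Replicate SES values per plot (default 3).
#' @param seed Integer seed.
#' @param depth_slope Fixed effect of water depth (default 0).
#' @return Tibble with columns `plot`, `water_depth_m`, `ses`.
#' @export
simulate_ses_table <- function(variances, hier, n_per_plot = 3, seed,
                               depth_slope = 0) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  need <- c("region", "lake", "depth", "plot", "residual")
  stopifnot(all(need %in% names(variances)))
  if (any(variances < 0)) stop("variances must be non-negative", call. = FALSE)
  hier <- validate_hierarchy(hier)
  set.seed(seed)
  eff <- function(labels, v) {
    u <- unique(labels)
    stats::setNames(stats::rnorm(length(u), 0, sqrt(v)), u)[labels]
  }
  base <- eff(hier$region, variances[["region"]]) +
    eff(hier$lake, variances[["lake"]]) +
    eff(hier$depth_stratum, variances[["depth"]]) +
    eff(hier$plot, variances[["plot"]]) +
    depth_slope * hier$water_depth_m
  out <- tibble::tibble(
    plot = rep(as.character(hier$plot), each = n_per_plot),
    water_depth_m = rep(hier$water_depth_m, each = n_per_plot)
  )
  out$ses <- rep(unname(base), each = n_per_plot) +
    stats::rnorm(nrow(out), 0, sqrt(variances[["residual"]]))
  out
}

#' Sample SES values from independent neutral communities
#'
#' Calibration utility: draws `n` plot communities, each from its own
#' neutral (`lambda = 0`) generator realization — independent species pool,
#' trait table and assembly — and returns the SES of the abundance-weighted
#' mean pairwise distance (PW) on the multi-trait Gower dendrogram, each
#' standardized against its own taxa-shuffle null. Because every community
#' carries an independent trait-to-species assignment, the returned values
#' are mutually independent, which is what group-level calibration checks
#' (mean SES, Wilcoxon rejection rate) require; communities within a single
#' survey share one assignment and are positively dependent (see the
#' methods vignette).
#'
#' @param n Number of communities.
#' @param n_iter Null iterations per community (default 999).
#' @param seed Integer seed; per-community seeds are derived from it.
#' @param pool_size Species-pool size (default 50).
#' @param target_richness Expected plot richness (default 5; the realized
#'   richness is constrained to at least 2 so every SES is defined).
#' @return Numeric vector of `n` SES values.
#' @export
neutral_ses_sample <- function(n, n_iter = 999, seed, pool_size = 50,
                               target_richness = 5) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  base <- as.integer(seed)
  vapply(seq_len(n), function(i) {
    scen <- scenario(seed = base + i, n_regions = 1, lakes_per_region = 1,
                     strata_per_lake = 1, plots_per_stratum = 1,
                     pool_size = pool_size, lambda = 0,
                     target_richness = target_richness,
                     richness_range = c(2, min(18, pool_size)))
    tr <- generate_traits(scen)
    sv <- generate_survey(scen, tr)
    dend <- build_dendrogram(gower_distance(tr))
    st <- ses_dispersion(sv$community, sv$hier, dend, scales = "plot",
                         metrics = "PW", n_iter = n_iter,
                         seed = base + 500000L + i)
    st$ses[1]
  }, numeric(1))
}
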