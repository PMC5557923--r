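#' Shuffle taxa labels on a species distance matrix
#'
#' The taxa-shuffle null model randomly reassigns species names to the tips
#' of the trait dendrogram: entry `(i, j)` of the shuffled matrix is the
#' original distance between the species the labels `i` and `j` were
#' reassigned to. The multiset of distances is unchanged, and community
#' matrices are untouched, so species richness, occupancy, abundances and
#' spatial distributions are all preserved by construction.
#'
#' @param dist Species distance matrix (or `trait_dendrogram`).
#' @param perm Optional integer permutation of `1:n` (for testing);
#'   default a uniformly random permutation drawn from the current RNG
#'   stream.
#' @return Shuffled distance matrix with the original dimnames.
#' @export
taxa_shuffle <- function(dist, perm = NULL) {
  D <- resolve_coph(dist)
  n <- nrow(D)
  if (is.null(perm)) perm <- sample.int(n)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  out <- D[perm, perm]
  dimnames(out) <- dimnames(D)
  out
}

#' Null distribution of a dispersion metric under taxa shuffling
#'
#' Applies `metric_fn` to `n_iter` independently shuffled distance matrices
#' and summarises the null sample. The observed value is not part of the
#' null sample.
#'
#' @param metric_fn Function of `(abund, dist)` — or `(abund_a, abund_b,
#'   dist)` when `abund` is a list of two communities — returning one value.
#' @param abund Named abundance vector, or a list of two such vectors for a
#'   beta metric.
#' @param dist Species distance matrix or `trait_dendrogram`.
#' @param n_iter Number of shuffles (default 999).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `mean`, `sd` (n - 1 denominator), `n_iter`, `values`.
#' @export
null_distribution <- function(metric_fn, abund, dist, n_iter = 999, seed = NULL) {
  stopifnot(n_iter >= 1)
  if (!is.null(seed)) set.seed(seed)
  D <- resolve_coph(dist)
  vals <- vapply(seq_len(n_iter), function(i) {
    Ds <- taxa_shuffle(D)
    if (is.list(abund)) metric_fn(abund[[1]], abund[[2]], Ds) else metric_fn(abund, Ds)
  }, numeric(1))
  list(mean = mean(vals), sd = stats::sd(vals), n_iter = n_iter, values = vals)
}

#' Standardized effect size of an observed metric against its null
#'
#' `SES = (Metric_obs - Metric_null) / Metric_SD`. Negative values indicate
#' functional under-dispersion (clustering, the signature of deterministic
#' abiotic filtering); positive values indicate over-dispersion. Undefined
#' (`NA`) when the observed value is undefined or the null SD is zero (e.g.
#' a community containing the whole species pool, for which every shuffle is
#' a relabelling of the same community).
#'
#' @param observed Observed metric value(s).
#' @param null_mean,null_sd Null mean and SD, recycled against `observed`.
#'   Alternatively `null_mean` may be a list returned by
#'   [null_distribution()].
#' @return Numeric SES value(s), `NA` where undefined.
#' @export
ses <- function(observed, null_mean, null_sd = NULL) {
  if (is.list(null_mean) && is.null(null_sd)) {
    null_sd <- null_mean$sd
    null_mean <- null_mean$mean
  }
  out <- (observed - null_mean) / null_sd
  # a null SD at floating-point noise level means every shuffle produced the
  # same value: the SES is undefined, not astronomically large
  degenerate <- !is.na(null_sd) &
    null_sd <= 1e-10 * pmax(1, abs(null_mean))
  out[degenerate] <- NA_real_
  out
}

#' Full SES dispersion analysis across scales and trait metrics
#'
#' For each trait dendrogram and each requested spatial scale, computes the
#' observed alpha (PW, NN) and/or beta (Dpw, Dnn) dispersion of the pooled
#' communities, the taxa-shuffle null mean and SD over `n_iter` iterations,
#' and the SES. Within an iteration a single pool-wide shuffle is shared by
#' all communities (and pairs), preserving cross-community structure for the
#' beta metrics.
#'
#' @param comm Community data at plot grain.
#' @param hier Spatial hierarchy.
#' @param dendrograms Named list of `trait_dendrogram`s (or distance
#'   matrices), e.g. from [build_all_dendrograms()]; names become the
#'   `trait_metric` column.
#' @param scales Character subset of `c("plot", "depth", "lake", "region")`.
#' @param metrics Character subset of `c("PW", "NN", "Dpw", "Dnn")`.
#' @param n_iter Null iterations (default 999).
#' @param seed Integer seed (required, for reproducibility).
#' @return A tibble of class `ses_table`: one row per trait metric x scale x
#'   metric x unit (or unit pair), with columns `trait_metric`, `scale`,
#'   `metric`, `unit`, `group`, `observed`, `null_mean`, `null_sd`, `ses`,
#'   `defined`. For beta metrics `unit` is `"a|b"` and `group` the enclosing
#'   unit.
#' @export
ses_dispersion <- function(comm, hier, dendrograms,
                           scales = c("plot", "depth", "lake", "region"),
                           metrics = c("PW", "NN", "Dpw", "Dnn"),
                           n_iter = 999, seed) {
  if (missing(seed)) stop("seed is required for reproducibility", call. = FALSE)
  stopifnot(n_iter >= 1)
  scales <- match.arg(scales, several.ok = TRUE)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (inherits(dendrograms, "trait_dendrogram") || is.matrix(dendrograms)) {
    dendrograms <- list(trait = dendrograms)
  }
  set.seed(seed)
  m <- as_community_matrix(comm)
  hier <- validate_hierarchy(hier)

  do_alpha <- any(c("PW", "NN") %in% metrics)
  do_beta <- any(c("Dpw", "Dnn") %in% metrics)

  res <- list()
  for (tm in names(dendrograms)) {
    D <- resolve_coph(dendrograms[[tm]])
    for (sc in scales) {
      pooled <- pool_to_scale(m, hier, sc)
      gmap <- scale_group_map(hier, sc)
      if (do_alpha) {
        cis <- apply(pooled, 1, function(r) {
          comm_index(stats::setNames(r, colnames(pooled)), rownames(D))
        }, simplify = FALSE)
        idx <- lapply(cis, `[[`, "idx"); w <- lapply(cis, `[[`, "w")
        obs <- alpha_metrics_cpp(idx, w, D)
        nul <- null_alpha_cpp(idx, w, D, n_iter)
        for (mt in intersect(c("PW", "NN"), metrics)) {
          s <- ses(obs[, mt], nul$mean[, mt], nul$sd[, mt])
          res[[length(res) + 1L]] <- tibble::tibble(
            trait_metric = tm, scale = sc, metric = mt,
            unit = rownames(pooled),
            group = gmap$group[match(rownames(pooled), gmap$unit)],
            observed = obs[, mt], null_mean = nul$mean[, mt],
            null_sd = nul$sd[, mt], ses = s, defined = !is.na(s)
          )
        }
      }
      if (do_beta) {
        pairs <- suppressMessages(scale_unit_pairs(hier, sc))
        pairs <- pairs[pairs$unit_a %in% rownames(pooled) &
                       pairs$unit_b %in% rownames(pooled), ]
        if (nrow(pairs) == 0L) next
        ci_of <- function(u) {
          comm_index(stats::setNames(pooled[u, ], colnames(pooled)), rownames(D))
        }
        ca <- lapply(pairs$unit_a, ci_of); cb <- lapply(pairs$unit_b, ci_of)
        ia <- lapply(ca, `[[`, "idx"); wa <- lapply(ca, `[[`, "w")
        ib <- lapply(cb, `[[`, "idx"); wb <- lapply(cb, `[[`, "w")
        obs <- beta_metrics_cpp(ia, wa, ib, wb, D)
        nul <- null_beta_cpp(ia, wa, ib, wb, D, n_iter)
        for (mt in intersect(c("Dpw", "Dnn"), metrics)) {
          s <- ses(obs[, mt], nul$mean[, mt], nul$sd[, mt])
          res[[length(res) + 1L]] <- tibble::tibble(
            trait_metric = tm, scale = sc, metric = mt,
            unit = paste(pairs$unit_a, pairs$unit_b, sep = "|"),
            group = pairs$group,
            observed = obs[, mt], null_mean = nul$mean[, mt],
            null_sd = nul$sd[, mt], ses = s, defined = !is.na(s)
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(res)
  class(out) <- c("ses_table", class(out))
  attr(out, "n_iter") <- n_iter
  attr(out, "seed") <- seed
  out
}

#' Significance stars at the 0.05 / 0.01 / 0.001 convention
#' @param p Numeric p-values.
#' @return Character vector of `""`, `"*"`, `"**"`, `"***"`.
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Wilcoxon signed-rank test of SES departure from zero
#'
#' Two-sided signed-rank test of the hypothesis that the SES values are
#' centred at zero (the expectation under random assembly). The exact null
#' distribution is used for n <= 25 without ties or zeros, otherwise the
#' normal approximation with continuity correction (the [stats::wilcox.test]
#' defaults).
#'
#' @param ses_values Numeric SES values; `NA`s (undefined SES) are dropped.
#' @return One-row tibble: `n`, `mean_ses`, `median_ses`, `statistic`,
#'   `p_value`, `direction` (`"clustered"`, `"over-dispersed"` or `"none"`),
#'   `stars`.
#' @export
wilcoxon_departure <- function(ses_values) {
  x <- ses_values[!is.na(ses_values)]
  if (length(x) < 5L) {
    stop("need at least 5 defined SES values (got ", length(x), ")",
         call. = FALSE)
  }
  if (all(x == 0)) stop("all SES values are exactly zero", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(x, mu = 0, exact = NULL,
                                            correct = TRUE))
  med <- stats::median(x)
  dir <- if (wt$p.value >= 0.05 || med == 0) "none"
         else if (med < 0) "clustered" else "over-dispersed"
  tibble::tibble(
    n = length(x), mean_ses = mean(x), median_ses = med,
    statistic = unname(wt$statistic), p_value = wt$p.value,
    direction = dir, stars = p_stars(wt$p.value)
  )
}

#' Group-level summary of an SES table
#'
#' Applies [wilcoxon_departure()] to each scale x trait-metric x metric cell
#' of an SES table (or to coarser groupings, e.g. pooling trait metrics with
#' `by = c("scale", "metric")`). Cells with fewer than 5 defined values are
#' returned with `NA` test results rather than an error.
#'
#' @param ses_tbl An SES table from [ses_dispersion()].
#' @param by Grouping columns (default `c("scale", "trait_metric",
#'   "metric")`).
#' @param adjust Multiple-testing adjustment across the summary rows:
#'   `"none"` (default, matching the star convention on raw p-values) or
#'   `"BH"`.
#' @return Tibble with the grouping columns plus the [wilcoxon_departure()]
#'   summary columns.
#' @export
summarize_departure <- function(ses_tbl,
                                by = c("scale", "trait_metric", "metric"),
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  out <- ses_tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(res = list({
      x <- .data$ses[!is.na(.data$ses)]
      if (length(x) < 5L || all(x == 0)) {
        tibble::tibble(n = length(x), mean_ses = mean(x), median_ses = stats::median(x),
                       statistic = NA_real_, p_value = NA_real_,
                       direction = NA_character_, stars = "")
      } else {
        wilcoxon_departure(x)
      }
    }), .groups = "drop") |>
    tidyr::unnest("res")
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$stars <- p_stars(out$p_adjusted)
  }
  out
}
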