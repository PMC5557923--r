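#' Nested variance components of SES values
#'
#' Decomposes the variance of plot-grain SES values over the spatial
#' hierarchy with a random-effects-only model (nested ANOVA with random
#' effects) fitted by REML: random intercepts for region, lake, depth
#' stratum and plot, with the residual interpreted as within-plot
#' (micro-habitat) variation. REML's non-negativity constraint replaces any
#' negative method-of-moments estimate by zero. Components are reported as
#' percentage shares of the total.
#'
#' @param data Data frame with a numeric `ses` column and a `plot` column
#'   (several rows per plot are allowed and identify the within-plot
#'   component; with exactly one row per plot the plot and within-plot
#'   components are confounded and split by the REML fit).
#' @param hier Spatial hierarchy (see [validate_hierarchy()]).
#' @return A `varcomp` tibble: `level` (region, lake, depth, plot,
#'   within_plot), `variance`, `share_pct`. Shares sum to 100 within
#'   tolerance.
#' @export
variance_partition <- function(data, hier) {
  hier <- validate_hierarchy(hier)
  stopifnot(all(c("ses", "plot") %in% names(data)))
  df <- dplyr::inner_join(
    dplyr::mutate(tibble::as_tibble(data), plot = as.character(.data$plot)),
    dplyr::mutate(hier, plot = as.character(.data$plot)),
    by = "plot"
  )
  if (nrow(df) == 0L) stop("no SES rows match the hierarchy plots", call. = FALSE)
  df <- df[!is.na(df$ses), ]
  fit <- lme4::lmer(
    ses ~ 1 + (1 | region) + (1 | lake) + (1 | depth_stratum) + (1 | plot),
    data = df,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                check.nobs.vs.nlev = "ignore",
                                check.nobs.vs.rankZ = "ignore",
                                check.nobs.vs.nRE = "ignore",
                                calc.derivs = FALSE)
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_var <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  vars <- c(
    region = get_var("region"),
    lake = get_var("lake"),
    depth = get_var("depth_stratum"),
    plot = get_var("plot"),
    within_plot = get_var("Residual")
  )
  out <- tibble::tibble(
    level = names(vars),
    variance = unname(vars),
    share_pct = 100 * unname(vars) / sum(vars)
  )
  class(out) <- c("varcomp", class(out))
  attr(out, "fit") <- fit
  out
}

#' PCA of the lake water-quality parameters
#'
#' Principal components of the per-lake physico-chemical records (Secchi
#' depth, total nitrogen, total phosphorus, chlorophyll-a, pH, water
#' temperature). Parameters are log-transformed (they must be positive) and
#' standardized to mean 0, SD 1 before the decomposition. The sign of axis 1
#' is oriented so that Secchi depth loads positively, making high scores
#' mean clearer, less eutrophic water.
#'
#' @param env Data frame with a `lake` column and numeric parameter columns.
#' @param log_transform Log-transform all parameters first (default `TRUE`).
#' @param orient_by Column whose axis-1 loading is forced positive (default
#'   `"secchi_depth"` when present, else the first parameter).
#' @return An `env_pca` object: list with `scores` (tibble, lake x axes),
#'   `loadings` (orthonormal matrix), `explained` (variance fractions,
#'   non-increasing, summing to 1), and the underlying `prcomp` fit.
#' @export
pca_environment <- function(env, log_transform = TRUE, orient_by = NULL) {
  stopifnot(is.data.frame(env), "lake" %in% names(env))
  params <- setdiff(names(env), "lake")
  x <- as.matrix(env[params])
  if (nrow(x) < 3L) stop("need at least 3 lakes", call. = FALSE)
  if (log_transform) {
    if (any(x <= 0)) stop("log transform requires positive values", call. = FALSE)
    x <- log(x)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant parameter(s): ",
         paste(params[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  if (is.null(orient_by)) {
    orient_by <- if ("secchi_depth" %in% params) "secchi_depth" else params[1]
  }
  if (pc$rotation[orient_by, 1] < 0) {
    pc$rotation[, 1] <- -pc$rotation[, 1]
    pc$x[, 1] <- -pc$x[, 1]
  }
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      scores = dplyr::bind_cols(tibble::tibble(lake = as.character(env$lake)),
                                tibble::as_tibble(pc$x)),
      loadings = pc$rotation,
      explained = explained,
      prcomp = pc
    ),
    class = "env_pca"
  )
}

#' @export
print.env_pca <- function(x, ...) {
  cat("<env_pca> ", nrow(x$scores), " lakes, ", ncol(x$loadings),
      " parameters; axis 1 explains ",
      sprintf("%.1f%%", 100 * x$explained[1]), "\n", sep = "")
  invisible(x)
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Split a gradient into equal-width levels
#'
#' Divides `[min(values), max(values)]` into `n_levels` intervals of equal
#' width. Level assignment uses the unrounded boundaries, with the maximum
#' included in the last level; `breaks_display` reports the boundaries
#' rounded half-up to 2 decimals, as the levels would be printed.
#'
#' @param values Numeric gradient values (e.g. per-lake log Secchi depth).
#' @param n_levels Number of levels (>= 1).
#' @return List with `breaks` (length `n_levels + 1`), `breaks_display`,
#'   and `levels` (integer level of each input value, 1-based).
#' @examples
#' bin_gradient(c(1.47, 2.0, 2.95), 5)$breaks_display
#' @export
bin_gradient <- function(values, n_levels) {
  stopifnot(n_levels >= 1, is.numeric(values))
  rng <- range(values)
  if (diff(rng) == 0) stop("degenerate gradient: max must exceed min", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = n_levels + 1L)
  lev <- findInterval(values, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  list(
    breaks = breaks,
    breaks_display = round_half_up(breaks, 2),
    levels = as.integer(lev)
  )
}

#' SES trend along an environmental gradient
#'
#' Fits a linear mixed model of SES on the gradient with a random intercept
#' for the enclosing spatial unit, and tests the gradient's fixed effect by
#' a likelihood-ratio test against the intercept-only nested model (both
#' fitted by maximum likelihood; the reported slope comes from the REML
#' refit). With fewer than two grouping levels — or no grouping — the model
#' falls back to ordinary least squares with a warning. A factor gradient
#' with two levels (e.g. low vs high elevation region) is handled as a
#' two-group contrast by the same machinery.
#'
#' A negative slope means the SES becomes more negative — communities more
#' clustered — along the gradient; the `direction` label is `"none"` when
#' p >= 0.05, otherwise `"more clustered"` (slope < 0) or `"less clustered"`
#' (slope > 0).
#'
#' @param data Data frame with a numeric `ses` column.
#' @param gradient Column (tidy-eval) holding the gradient value per row;
#'   numeric, or factor/character for a level contrast.
#' @param group Optional column (tidy-eval) of random-intercept labels.
#' @return A `gradient_trend` one-row tibble: `slope`, `se`, `statistic`
#'   (likelihood-ratio chi-square), `df`, `p_value`, `direction`, `stars`,
#'   `n`, `n_groups`, `method` (`"lmm"` or `"ols"`), `singular`.
#' @export
gradient_trend <- function(data, gradient, group = NULL) {
  stopifnot("ses" %in% names(data))
  df <- tibble::tibble(
    ses = data$ses,
    g = rlang::eval_tidy(rlang::enquo(gradient), data)
  )
  grp <- rlang::eval_tidy(rlang::enquo(group), data)
  has_grp <- !is.null(grp)
  if (has_grp) df$grp <- as.factor(grp)
  df <- df[stats::complete.cases(df), ]
  n <- nrow(df)
  if (is.character(df$g)) df$g <- factor(df$g)
  if (is.factor(df$g) && nlevels(droplevels(df$g)) < 2L) {
    stop("gradient needs at least 2 levels", call. = FALSE)
  }

  trend_row <- function(slope, se, stat, dfree, p, method, n_groups, singular) {
    dir <- if (is.na(p) || p >= 0.05 || slope == 0) "none"
           else if (slope < 0) "more clustered" else "less clustered"
    out <- tibble::tibble(
      slope = slope, se = se, statistic = stat, df = dfree, p_value = p,
      direction = dir, stars = p_stars(p), n = n, n_groups = n_groups,
      method = method, singular = singular
    )
    class(out) <- c("gradient_trend", class(out))
    out
  }

  if (stats::var(df$ses) == 0) {
    return(trend_row(0, NA_real_, NA_real_, NA_real_, 1, "degenerate",
                     if (has_grp) nlevels(df$grp) else 0L, FALSE))
  }

  use_lmm <- has_grp && nlevels(droplevels(df$grp)) >= 2L
  if (use_lmm) {
    ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
    m1 <- try(lme4::lmer(ses ~ g + (1 | grp), data = df, REML = FALSE,
                         control = ctrl), silent = TRUE)
    m0 <- try(lme4::lmer(ses ~ 1 + (1 | grp), data = df, REML = FALSE,
                         control = ctrl), silent = TRUE)
    if (!inherits(m1, "try-error") && !inherits(m0, "try-error")) {
      lrt <- stats::anova(m0, m1)
      mr <- lme4::lmer(ses ~ g + (1 | grp), data = df, REML = TRUE,
                       control = ctrl)
      cf <- summary(mr)$coefficients
      singular <- lme4::isSingular(mr)
      return(trend_row(cf[2, "Estimate"], cf[2, "Std. Error"],
                       lrt$Chisq[2], lrt$Df[2], lrt$`Pr(>Chisq)`[2],
                       "lmm", nlevels(droplevels(df$grp)), singular))
    }
    warning("mixed-model fit failed; falling back to ordinary least squares",
            call. = FALSE)
  } else if (has_grp) {
    warning("fewer than 2 grouping levels; using ordinary least squares",
            call. = FALSE)
  }
  m1 <- stats::lm(ses ~ g, data = df)
  m0 <- stats::lm(ses ~ 1, data = df)
  stat <- as.numeric(2 * (stats::logLik(m1) - stats::logLik(m0)))
  dfree <- attr(stats::logLik(m1), "df") - attr(stats::logLik(m0), "df")
  p <- stats::pchisq(stat, df = dfree, lower.tail = FALSE)
  cf <- summary(m1)$coefficients
  trend_row(cf[2, "Estimate"], cf[2, "Std. Error"], stat, dfree, p, "ols",
            if (has_grp) nlevels(droplevels(df$grp)) else 0L, FALSE)
}

# gradient value of a beta pair = mean of its two units' values
pair_gradient <- function(unit, gradient_by_unit) {
  parts <- strsplit(unit, "|", fixed = TRUE)
  vapply(parts, function(p) mean(gradient_by_unit[p]), numeric(1))
}

#' Scale-specific gradient trends for every trait metric and SES metric
#'
#' Convenience wrapper running [gradient_trend()] over each trait metric x
#' SES metric cell of an SES table, with the gradient and random-effect
#' structure the survey design implies at each scale:
#' \describe{
#'   \item{depth}{SES of depth-stratum units against stratum water depth,
#'     random intercept for lake.}
#'   \item{lake}{SES of lake units against log Secchi depth (water
#'     transparency), random intercept for region.}
#'   \item{region}{SES of lake units contrasted between the two elevation
#'     levels (low/high region); with region as both the contrast and the
#'     only grouping this is an ordinary two-group comparison.}
#' }
#' Beta-metric pairs receive the mean gradient value of their two units.
#'
#' @param ses_tbl SES table from [ses_dispersion()].
#' @param hier Spatial hierarchy.
#' @param env Per-lake environment table (needed for the lake scale);
#'   must contain `lake` and `secchi_depth`.
#' @param scale One of `"depth"`, `"lake"`, `"region"`.
#' @return Tibble: `scale`, `trait_metric`, `metric`, plus the
#'   [gradient_trend()] columns.
#' @export
scale_gradient_trends <- function(ses_tbl, hier, env = NULL,
                                  scale = c("depth", "lake", "region")) {
  scale <- match.arg(scale)
  hier <- validate_hierarchy(hier)

  if (scale == "depth") {
    sub <- ses_tbl[ses_tbl$scale == "depth", ]
    gmap <- unique(tibble::tibble(unit = as.character(hier$depth_stratum),
                                  value = hier$water_depth_m,
                                  grp = as.character(hier$lake)))
    grad <- stats::setNames(gmap$value, gmap$unit)
    grpmap <- stats::setNames(gmap$grp, gmap$unit)
  } else if (scale == "lake") {
    if (is.null(env) || !"secchi_depth" %in% names(env)) {
      stop("lake-scale trends need an env table with secchi_depth", call. = FALSE)
    }
    sub <- ses_tbl[ses_tbl$scale == "lake", ]
    grad <- stats::setNames(log(env$secchi_depth), as.character(env$lake))
    gmap <- unique(tibble::tibble(unit = as.character(hier$lake),
                                  grp = as.character(hier$region)))
    grpmap <- stats::setNames(gmap$grp, gmap$unit)
  } else {
    # two-level elevation contrast on lake-scale SES values
    sub <- ses_tbl[ses_tbl$scale == "lake", ]
    emap <- unique(tibble::tibble(lake = as.character(hier$lake),
                                  region = as.character(hier$region),
                                  elev = hier$elevation_m))
    lev <- sort(unique(emap$elev))
    emap$band <- ifelse(emap$elev == max(emap$elev), "high_elevation",
                        "low_elevation")
    grad <- stats::setNames(factor(emap$band,
                                   levels = c("low_elevation", "high_elevation")),
                            emap$lake)
    grpmap <- NULL
  }

  sub |>
    dplyr::group_by(.data$trait_metric, .data$metric) |>
    dplyr::group_modify(function(d, key) {
      is_pair <- grepl("|", d$unit, fixed = TRUE)
      gv <- if (any(is_pair)) {
        if (is.factor(grad)) {
          # a pair straddling levels is dropped; within-level pairs keep it
          lv <- strsplit(d$unit, "|", fixed = TRUE)
          vapply(lv, function(p) {
            u <- unique(as.character(grad[p]))
            if (length(u) == 1L) u else NA_character_
          }, character(1))
        } else {
          pair_gradient(d$unit, grad)
        }
      } else {
        if (is.factor(grad)) as.character(grad[d$unit]) else unname(grad[d$unit])
      }
      d$gradient <- gv
      d$grp <- if (is.null(grpmap)) NULL else {
        if (any(is_pair)) {
          vapply(strsplit(d$unit, "|", fixed = TRUE),
                 function(p) grpmap[p[1]], character(1))
        } else unname(grpmap[d$unit])
      }
      res <- try(
        if (is.null(grpmap)) {
          suppressWarnings(gradient_trend(d, gradient))
        } else {
          suppressWarnings(gradient_trend(d, gradient, grp))
        },
        silent = TRUE
      )
      if (inherits(res, "try-error")) {
        tibble::tibble(slope = NA_real_, se = NA_real_, statistic = NA_real_,
                       df = NA_real_, p_value = NA_real_, direction = NA_character_,
                       stars = "", n = nrow(d), n_groups = NA_integer_,
                       method = "failed", singular = NA)
      } else res
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(scale = scale, .before = 1)
}
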