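#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy the loadings of an environment PCA
#' @param x An `env_pca` object.
#' @param ... Unused.
#' @return Tibble with columns `parameter`, `axis`, `loading`.
#' @method tidy env_pca
#' @export
tidy.env_pca <- function(x, ...) {
  L <- x$loadings
  tibble::tibble(
    parameter = rep(rownames(L), times = ncol(L)),
    axis = rep(colnames(L), each = nrow(L)),
    loading = as.vector(L)
  )
}

#' One-row summary of an environment PCA
#' @param x An `env_pca` object.
#' @param ... Unused.
#' @return Tibble with `n_lakes`, `n_parameters`, `axis1_explained`,
#'   `axis2_explained`.
#' @method glance env_pca
#' @export
glance.env_pca <- function(x, ...) {
  tibble::tibble(
    n_lakes = nrow(x$scores),
    n_parameters = nrow(x$loadings),
    axis1_explained = x$explained[1],
    axis2_explained = if (length(x$explained) > 1) x$explained[2] else NA_real_
  )
}

#' Tidy the merge heights of a trait dendrogram
#' @param x A `trait_dendrogram`.
#' @param ... Unused.
#' @return Tibble with `step`, `height`.
#' @method tidy trait_dendrogram
#' @export
tidy.trait_dendrogram <- function(x, ...) {
  tibble::tibble(step = seq_along(x$hclust$height), height = x$hclust$height)
}

#' One-row summary of a variance-component decomposition
#' @param x A `varcomp` tibble.
#' @param ... Unused.
#' @return Tibble with `total_variance`, `dominant_level`,
#'   `dominant_share_pct`.
#' @method glance varcomp
#' @export
glance.varcomp <- function(x, ...) {
  i <- which.max(x$share_pct)
  tibble::tibble(
    total_variance = sum(x$variance),
    dominant_level = x$level[i],
    dominant_share_pct = x$share_pct[i]
  )
}

#' Plot mean SES by spatial scale and trait metric
#'
#' Point-and-line display of the mean SES of each trait metric across the
#' nested scales, faceted by dispersion metric, with the zero line of the
#' null expectation; values below zero indicate functional clustering.
#'
#' @param object An SES table from [ses_dispersion()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ses_table
#' @export
autoplot.ses_table <- function(object, ...) {
  dat <- object |>
    dplyr::filter(.data$defined) |>
    dplyr::group_by(.data$scale, .data$trait_metric, .data$metric) |>
    dplyr::summarise(mean_ses = mean(.data$ses), .groups = "drop") |>
    dplyr::mutate(scale = factor(.data$scale,
                                 levels = c("plot", "depth", "lake", "region")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$scale, y = .data$mean_ses,
                                    colour = .data$trait_metric,
                                    group = .data$trait_metric)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "spatial scale", y = "mean SES",
                  colour = "trait metric") +
    ggplot2::theme_minimal()
}

#' Bar chart of variance-component shares
#' @param object A `varcomp` tibble from [variance_partition()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot varcomp
#' @export
autoplot.varcomp <- function(object, ...) {
  dat <- dplyr::mutate(
    tibble::as_tibble(object),
    level = factor(.data$level,
                   levels = c("region", "lake", "depth", "plot", "within_plot"))
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$level, y = .data$share_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "hierarchy level", y = "variance share (%)") +
    ggplot2::theme_minimal()
}

#' Plot SES against a gradient with the fitted trend
#'
#' @param data Data frame with `ses` and the gradient column.
#' @param gradient Column (tidy-eval) of gradient values.
#' @param trend Optional `gradient_trend` row to annotate slope and stars.
#' @return A ggplot object.
#' @export
plot_gradient_ses <- function(data, gradient, trend = NULL) {
  g <- rlang::enquo(gradient)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = !!g, y = .data$ses)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "firebrick") +
    ggplot2::labs(y = "SES") +
    ggplot2::theme_minimal()
  if (!is.null(trend)) {
    p <- p + ggplot2::ggtitle(
      sprintf("slope = %.3f %s (%s)", trend$slope, trend$stars, trend$direction)
    )
  }
  p
}
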