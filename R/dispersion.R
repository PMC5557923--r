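#' @useDynLib fundisp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# named abundance vector -> 0-based index + relative weights on D's labels
comm_index <- function(abund, species) {
  abund <- abund[abund > 0]
  miss <- setdiff(names(abund), species)
  if (length(miss)) {
    stop("species absent from distance matrix: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  idx <- match(names(abund), species) - 1L
  list(idx = as.integer(idx), w = as.numeric(abund / sum(abund)))
}

resolve_coph <- function(dist) {
  if (inherits(dist, "trait_dendrogram")) dist <- dist$cophenetic
  check_dist_matrix(dist)
}

#' Abundance-weighted mean pairwise trait distance (PW) of one community
#'
#' `PW = sum_{i != j} f_i f_j d_ij / sum_{i != j} f_i f_j`, where `f` are
#' the relative abundances of the species present and `d` the inter-species
#' distances (usually cophenetic distances of a trait dendrogram). Invariant
#' to rescaling all abundances by a constant. Undefined (`NA`) for
#' communities with fewer than two species present.
#'
#' @param abund Named numeric vector of abundances (names are species).
#' @param dist Species distance matrix or a `trait_dendrogram`.
#' @return A single numeric value; `NA` if undefined.
#' @export
alpha_pw <- function(abund, dist) {
  D <- resolve_coph(dist)
  ci <- comm_index(abund, rownames(D))
  if (length(ci$idx) < 2L) return(NA_real_)
  unname(alpha_metrics_cpp(list(ci$idx), list(ci$w), D)[1, "PW"])
}

#' Abundance-weighted nearest-neighbour trait distance (NN) of one community
#'
#' `NN = sum_i f_i min_{j != i} d_ij` over the species present, with `f`
#' relative abundances. Always `NN <= PW`. `NA` for communities with fewer
#' than two species.
#'
#' @inheritParams alpha_pw
#' @return A single numeric value; `NA` if undefined.
#' @export
alpha_nn <- function(abund, dist) {
  D <- resolve_coph(dist)
  ci <- comm_index(abund, rownames(D))
  if (length(ci$idx) < 2L) return(NA_real_)
  unname(alpha_metrics_cpp(list(ci$idx), list(ci$w), D)[1, "NN"])
}

#' Mean pairwise functional dissimilarity (Dpw) between two communities
#'
#' `Dpw = sum_{i in A} sum_{j in B} f_iA f_jB d_ij` with relative abundances
#' within each community; symmetric in the pair by construction.
#'
#' @param abund_a,abund_b Named abundance vectors of the two communities.
#' @inheritParams alpha_pw
#' @return A single numeric value.
#' @export
beta_dpw <- function(abund_a, abund_b, dist) {
  D <- resolve_coph(dist)
  ca <- comm_index(abund_a, rownames(D))
  cb <- comm_index(abund_b, rownames(D))
  if (length(ca$idx) == 0L || length(cb$idx) == 0L) {
    stop("both communities must be non-empty", call. = FALSE)
  }
  unname(beta_metrics_cpp(list(ca$idx), list(ca$w), list(cb$idx), list(cb$w), D)[1, "Dpw"])
}

#' Mean nearest-neighbour functional dissimilarity (Dnn) between two
#' communities
#'
#' The mean of the two directed nearest-neighbour sums,
#' `Dnn = 0.5 * (sum_{i in A} f_iA min_{j in B} d_ij +
#' sum_{j in B} f_jB min_{i in A} d_ij)`, so that the value is symmetric in
#' the pair and `Dnn(A, A) = 0`.
#'
#' @inheritParams beta_dpw
#' @return A single numeric value.
#' @export
beta_dnn <- function(abund_a, abund_b, dist) {
  D <- resolve_coph(dist)
  ca <- comm_index(abund_a, rownames(D))
  cb <- comm_index(abund_b, rownames(D))
  if (length(ca$idx) == 0L || length(cb$idx) == 0L) {
    stop("both communities must be non-empty", call. = FALSE)
  }
  unname(beta_metrics_cpp(list(ca$idx), list(ca$w), list(cb$idx), list(cb$w), D)[1, "Dnn"])
}

#' Alpha dispersion of every community in a matrix
#'
#' @param comm Community data (rows are sampling units).
#' @inheritParams alpha_pw
#' @return Tibble with columns `sample`, `metric` (`PW`/`NN`), `value`,
#'   `defined`.
#' @export
alpha_dispersion <- function(comm, dist) {
  D <- resolve_coph(dist)
  m <- as_community_matrix(comm)
  cis <- apply(m, 1, function(r) comm_index(stats::setNames(r, colnames(m)), rownames(D)),
               simplify = FALSE)
  vals <- alpha_metrics_cpp(lapply(cis, `[[`, "idx"), lapply(cis, `[[`, "w"), D)
  tibble::tibble(
    sample = rep(rownames(m), 2L),
    metric = rep(c("PW", "NN"), each = nrow(m)),
    value = c(vals[, "PW"], vals[, "NN"]),
    defined = !is.na(c(vals[, "PW"], vals[, "NN"]))
  )
}

# unit -> parent group mapping for within-group beta comparisons
scale_group_map <- function(hier, scale) {
  hier <- validate_hierarchy(hier)
  switch(scale,
    plot = tibble::tibble(unit = as.character(hier$plot),
                          group = as.character(hier$depth_stratum)),
    depth = unique(tibble::tibble(unit = as.character(hier$depth_stratum),
                                  group = as.character(hier$lake))),
    lake = unique(tibble::tibble(unit = as.character(hier$lake),
                                 group = as.character(hier$region))),
    region = unique(tibble::tibble(unit = as.character(hier$region),
                                   group = "study")),
    stop("unknown scale: ", scale, call. = FALSE)
  )
}

# all unordered within-group unit pairs at a scale; groups with < 2 units
# are skipped with a message
scale_unit_pairs <- function(hier, scale) {
  map <- scale_group_map(hier, scale)
  pairs <- map |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(pair = list({
      u <- sort(unique(.data$unit))
      if (length(u) < 2L) {
        tibble::tibble(unit_a = character(0), unit_b = character(0))
      } else {
        cmb <- utils::combn(u, 2L)
        tibble::tibble(unit_a = cmb[1, ], unit_b = cmb[2, ])
      }
    }), .groups = "drop") |>
    tidyr::unnest("pair")
  skipped <- setdiff(unique(map$group), unique(pairs$group))
  if (length(skipped)) {
    message("skipping group(s) with < 2 sub-units: ",
            paste(utils::head(skipped, 5), collapse = ", "))
  }
  pairs
}

#' Between-community dispersion for all within-group pairs at a scale
#'
#' Pools the community matrix to the requested scale and evaluates Dpw and
#' Dnn for every unordered pair of units sharing the same enclosing group
#' (plots within a depth stratum, strata within a lake, lakes within a
#' region, and the regions themselves). Groups with fewer than two units are
#' skipped with a message.
#'
#' @inheritParams pool_to_scale
#' @inheritParams alpha_pw
#' @return Tibble with columns `scale`, `group`, `unit_a`, `unit_b`,
#'   `metric` (`Dpw`/`Dnn`), `value`.
#' @export
beta_within_group <- function(comm, hier, scale, dist) {
  D <- resolve_coph(dist)
  pooled <- pool_to_scale(comm, hier, scale)
  pairs <- scale_unit_pairs(hier, scale)
  pairs <- pairs[pairs$unit_a %in% rownames(pooled) &
                 pairs$unit_b %in% rownames(pooled), ]
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(scale = character(0), group = character(0),
                          unit_a = character(0), unit_b = character(0),
                          metric = character(0), value = numeric(0)))
  }
  ci_of <- function(u) comm_index(stats::setNames(pooled[u, ], colnames(pooled)),
                                  rownames(D))
  ca <- lapply(pairs$unit_a, ci_of)
  cb <- lapply(pairs$unit_b, ci_of)
  vals <- beta_metrics_cpp(lapply(ca, `[[`, "idx"), lapply(ca, `[[`, "w"),
                           lapply(cb, `[[`, "idx"), lapply(cb, `[[`, "w"), D)
  tibble::tibble(
    scale = scale,
    group = rep(pairs$group, 2L),
    unit_a = rep(pairs$unit_a, 2L),
    unit_b = rep(pairs$unit_b, 2L),
    metric = rep(c("Dpw", "Dnn"), each = nrow(pairs)),
    value = c(vals[, "Dpw"], vals[, "Dnn"])
  )
}
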