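#' Validate a species-by-trait table
#'
#' Checks a trait table against its declared trait types: every species must
#' have a value for every declared trait, continuous values must be finite,
#' categorical values must come from the declared level set, and species
#' labels must be unique.
#'
#' @param traits A data frame with a `species` column and one column per
#'   trait.
#' @param types Named character vector mapping trait names to `"continuous"`
#'   or `"categorical"`. If `NULL`, types are taken from the table's
#'   `trait_types` attribute (set by [read_trait_table()]) or inferred from
#'   column classes (numeric columns are continuous).
#' @return The validated table (invisibly unchanged apart from attributes),
#'   with `trait_types` attached.
#' @export
validate_trait_table <- function(traits, types = NULL) {
  stopifnot(is.data.frame(traits))
  if (!"species" %in% names(traits)) {
    stop("trait table must have a 'species' column", call. = FALSE)
  }
  if (anyDuplicated(traits$species)) {
    stop("species labels must be unique", call. = FALSE)
  }
  types <- resolve_trait_types(traits, types)
  for (tr in names(types)) {
    if (!tr %in% names(traits)) {
      stop("declared trait '", tr, "' missing from table", call. = FALSE)
    }
    x <- traits[[tr]]
    if (anyNA(x)) stop("missing values in trait '", tr, "'", call. = FALSE)
    if (types[[tr]] == "continuous") {
      if (!is.numeric(x) || any(!is.finite(x))) {
        stop("continuous trait '", tr, "' has non-finite or non-numeric values",
             call. = FALSE)
      }
    }
  }
  attr(traits, "trait_types") <- types
  traits
}

resolve_trait_types <- function(traits, types = NULL) {
  if (is.null(types)) types <- attr(traits, "trait_types")
  if (is.null(types)) {
    cols <- setdiff(names(traits), "species")
    types <- vapply(
      traits[cols],
      function(x) if (is.numeric(x)) "continuous" else "categorical",
      character(1)
    )
  }
  bad <- setdiff(types, c("continuous", "categorical"))
  if (length(bad)) stop("unknown trait type: ", bad[1], call. = FALSE)
  types
}

#' Gower distance between species on mixed trait data
#'
#' Pairwise Gower dissimilarity: per-trait contributions are
#' `|x_i - x_j| / range` for continuous traits and a 0/1 mismatch indicator
#' for categorical traits, combined as an unweighted mean over traits. All
#' entries lie in `[0, 1]`. A trait with zero range contributes 0 to every
#' pair and is reported via a warning and the `constant_traits` attribute;
#' if every requested trait is constant the distance is undefined and an
#' error is raised.
#'
#' @inheritParams validate_trait_table
#' @param traits_use Character vector of trait names to use; default all
#'   declared traits.
#' @return A symmetric species-by-species distance matrix with dimnames,
#'   attributes `metric = "gower"` and `constant_traits`.
#' @examples
#' tr <- tibble::tibble(
#'   species = c("a", "b"),
#'   life_history = c("annual", "perennial"),
#'   shoot_height = c(10, 30)
#' )
#' gower_distance(tr)
#' @export
gower_distance <- function(traits, types = NULL, traits_use = NULL) {
  traits <- validate_trait_table(traits, types)
  types <- attr(traits, "trait_types")
  if (is.null(traits_use)) traits_use <- names(types)
  unknown <- setdiff(traits_use, names(types))
  if (length(unknown)) {
    stop("unknown trait name: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(traits_use) == 0L) stop("traits_use must be non-empty", call. = FALSE)
  n <- nrow(traits)
  if (n < 2L) stop("need at least 2 species", call. = FALSE)

  contribs <- array(0, dim = c(n, n, length(traits_use)))
  constant <- character(0)
  for (k in seq_along(traits_use)) {
    tr <- traits_use[[k]]
    x <- traits[[tr]]
    if (types[[tr]] == "continuous") {
      rng <- diff(range(x))
      if (rng == 0) {
        constant <- c(constant, tr)
        next # contribution stays 0
      }
      contribs[, , k] <- abs(outer(x, x, "-")) / rng
    } else {
      x <- as.character(x)
      if (length(unique(x)) == 1L) {
        constant <- c(constant, tr)
        next
      }
      contribs[, , k] <- outer(x, x, "!=") * 1
    }
  }
  if (length(constant) == length(traits_use)) {
    stop("all traits are constant; Gower distance undefined", call. = FALSE)
  }
  if (length(constant)) {
    warning("constant trait(s) contribute zero distance: ",
            paste(constant, collapse = ", "), call. = FALSE)
  }
  d <- apply(contribs, c(1, 2), mean)
  dimnames(d) <- list(traits$species, traits$species)
  structure(d, metric = "gower", constant_traits = constant)
}

#' Euclidean distance on a single standardized continuous trait
#'
#' The trait is z-standardized (mean 0, SD 1) across the species pool before
#' taking absolute differences, so that dendrogram heights — and hence SES
#' magnitudes — are comparable across traits measured in different units.
#'
#' @inheritParams validate_trait_table
#' @param trait Name of one continuous trait.
#' @return A symmetric distance matrix with attribute `metric = "euclidean"`.
#' @export
euclidean_distance <- function(traits, trait, types = NULL) {
  traits <- validate_trait_table(traits, types)
  types <- attr(traits, "trait_types")
  if (!trait %in% names(types)) stop("unknown trait name: ", trait, call. = FALSE)
  if (types[[trait]] != "categorical" && !is.numeric(traits[[trait]])) {
    stop("trait '", trait, "' is not numeric", call. = FALSE)
  }
  if (types[[trait]] == "categorical") {
    stop("trait '", trait, "' is categorical; use gower_distance()", call. = FALSE)
  }
  if (nrow(traits) < 2L) stop("need at least 2 species", call. = FALSE)
  x <- traits[[trait]]
  if (stats::sd(x) == 0) stop("trait '", trait, "' has zero variance", call. = FALSE)
  z <- as.numeric(scale(x))
  d <- abs(outer(z, z, "-"))
  dimnames(d) <- list(traits$species, traits$species)
  structure(d, metric = "euclidean")
}

#' Build an ultrametric trait dendrogram by hierarchical clustering
#'
#' Clusters the species distance matrix (UPGMA / average linkage by default)
#' and exposes the cophenetic distance matrix, which is the inter-species
#' distance used by all downstream dispersion metrics, plus an [ape::phylo]
#' representation for Newick export.
#'
#' @param dist Symmetric non-negative species distance matrix with dimnames.
#' @param method Linkage: `"average"` (UPGMA, default), `"complete"` or
#'   `"single"` for sensitivity checks.
#' @return A `trait_dendrogram` object: list with elements `hclust`,
#'   `cophenetic` (matrix), `phylo`, `method`.
#' @export
build_dendrogram <- function(dist, method = c("average", "complete", "single")) {
  method <- match.arg(method)
  dist <- check_dist_matrix(dist)
  hc <- stats::hclust(stats::as.dist(dist), method = method)
  coph <- as.matrix(stats::cophenetic(hc))
  coph <- coph[rownames(dist), rownames(dist)]
  structure(
    list(
      hclust = hc,
      cophenetic = coph,
      phylo = ape::as.phylo(hc),
      method = method
    ),
    class = "trait_dendrogram"
  )
}

check_dist_matrix <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) < 2L) stop("need at least 2 species", call. = FALSE)
  if (is.null(rownames(dist))) stop("distance matrix needs species dimnames", call. = FALSE)
  if (!isSymmetric(unname(dist), tol = 1e-10)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(dist < 0)) stop("distances must be non-negative", call. = FALSE)
  if (any(diag(dist) != 0)) stop("distance diagonal must be zero", call. = FALSE)
  dist
}

#' @export
print.trait_dendrogram <- function(x, ...) {
  cat("<trait_dendrogram> ", length(x$hclust$labels), " species, ",
      x$method, " linkage, max height ", format(max(x$hclust$height)),
      "\n", sep = "")
  invisible(x)
}

#' Cophenetic distances of a trait dendrogram
#' @param dend A `trait_dendrogram`.
#' @return Symmetric ultrametric distance matrix.
#' @export
cophenetic_matrix <- function(dend) {
  stopifnot(inherits(dend, "trait_dendrogram"))
  dend$cophenetic
}

#' Write a dendrogram as Newick
#' @param dend A `trait_dendrogram`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dend, path) {
  stopifnot(inherits(dend, "trait_dendrogram"))
  ape::write.tree(dend$phylo, file = path)
  invisible(path)
}

#' Build the full set of trait dendrograms
#'
#' One dendrogram per single trait — Gower distance for categorical traits,
#' Euclidean distance on the z-standardized values for continuous traits —
#' plus one multi-trait dendrogram from the Gower distance over all traits.
#'
#' @inheritParams validate_trait_table
#' @param method Linkage passed to [build_dendrogram()].
#' @return Named list of `trait_dendrogram` objects: one per trait and one
#'   `"multi_trait"`.
#' @export
build_all_dendrograms <- function(traits, types = NULL, method = "average") {
  traits <- validate_trait_table(traits, types)
  types <- attr(traits, "trait_types")
  out <- lapply(names(types), function(tr) {
    d <- if (types[[tr]] == "categorical") {
      gower_distance(traits, traits_use = tr)
    } else {
      euclidean_distance(traits, tr)
    }
    build_dendrogram(d, method = method)
  })
  names(out) <- names(types)
  out$multi_trait <- build_dendrogram(gower_distance(traits), method = method)
  out
}

#' Tidy a distance matrix into a long tibble
#'
#' @param d Symmetric distance matrix with dimnames.
#' @param upper_only Keep only one row per unordered pair (default `TRUE`).
#' @return Tibble with columns `species_a`, `species_b`, `distance`.
#' @export
tidy_dist <- function(d, upper_only = TRUE) {
  d <- as.matrix(d)
  out <- tibble::tibble(
    species_a = rep(rownames(d), times = ncol(d)),
    species_b = rep(colnames(d), each = nrow(d)),
    distance = as.vector(d)
  )
  if (upper_only) {
    keep <- as.vector(row(d) < col(d))
    out <- out[keep, ]
  }
  out
}

#' Check the ultrametric triple inequality on a distance matrix
#'
#' For every triple (a, b, c): `d(a,b) <= max(d(a,c), d(b,c))`. Cophenetic
#' matrices of hierarchical clusterings satisfy this by construction; the
#' check is exposed for validation and testing.
#'
#' @param d Symmetric distance matrix.
#' @param tol Numeric tolerance.
#' @return `TRUE` if ultrametric, else `FALSE`.
#' @export
is_ultrametric <- function(d, tol = 1e-8) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) return(TRUE)
  for (a in seq_len(n - 2L)) {
    for (b in seq(a + 1L, n - 1L)) {
      cc <- seq(b + 1L, n)
      m <- pmin(
        pmax(d[a, cc], d[b, cc]) - d[a, b],
        pmax(d[a, b], d[b, cc]) - d[a, cc],
        pmax(d[a, b], d[a, cc]) - d[b, cc]
      )
      if (any(m < -tol)) return(FALSE)
    }
  }
  TRUE
}
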