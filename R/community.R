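#' Coerce a community table to an abundance matrix
#'
#' Accepts either a numeric matrix (samples x species, with dimnames) or a
#' data frame whose first column (or a column named `sample`) holds sample
#' labels and whose remaining columns are species abundances.
#'
#' @param comm Community data (data frame or matrix).
#' @param drop_empty Drop all-zero sample rows with a message (default
#'   `TRUE`), mirroring survey records where no individual was found.
#' @return Numeric matrix, samples as rows.
#' @export
as_community_matrix <- function(comm, drop_empty = TRUE) {
  if (is.data.frame(comm)) {
    id_col <- if ("sample" %in% names(comm)) "sample" else names(comm)[1]
    m <- as.matrix(comm[setdiff(names(comm), id_col)])
    rownames(m) <- as.character(comm[[id_col]])
  } else {
    m <- as.matrix(comm)
  }
  storage.mode(m) <- "double"
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("community matrix needs sample and species labels", call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("abundances must be finite and non-negative", call. = FALSE)
  }
  empty <- rowSums(m) == 0
  if (any(empty) && drop_empty) {
    message("dropping ", sum(empty), " all-zero sample(s): ",
            paste(utils::head(rownames(m)[empty], 5), collapse = ", "))
    m <- m[!empty, , drop = FALSE]
  }
  m
}

#' Validate a spatial hierarchy table
#'
#' The hierarchy maps each plot to its depth stratum, lake and region, and
#' carries the stratum water depth (m) and region elevation (m a.s.l.). The
#' mapping must be a tree: a plot belongs to exactly one stratum, a stratum
#' to one lake, a lake to one region.
#'
#' @param hier Data frame with columns `plot`, `depth_stratum`,
#'   `water_depth_m`, `lake`, `region`, `elevation_m`.
#' @return The validated tibble.
#' @export
validate_hierarchy <- function(hier) {
  need <- c("plot", "depth_stratum", "water_depth_m", "lake", "region",
            "elevation_m")
  miss <- setdiff(need, names(hier))
  if (length(miss)) {
    stop("hierarchy missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  hier <- tibble::as_tibble(hier)
  if (anyDuplicated(hier$plot)) stop("duplicate plot ids", call. = FALSE)
  check_nested <- function(child, parent, what) {
    tab <- unique(hier[, c(child, parent)])
    if (anyDuplicated(tab[[child]])) {
      stop(what, " assigned to more than one parent unit", call. = FALSE)
    }
  }
  check_nested("lake", "region", "lake")
  # stratum ids are often the depth value, reused across lakes; qualify them
  tab <- unique(hier[, c("depth_stratum", "lake")])
  if (anyDuplicated(tab$depth_stratum)) {
    hier$depth_stratum <- paste(hier$lake, hier$depth_stratum, sep = ":")
  }
  if (any(hier$water_depth_m <= 0)) stop("water depth must be > 0", call. = FALSE)
  if (any(!is.finite(hier$elevation_m))) stop("elevation must be finite", call. = FALSE)
  hier
}

#' Pool a community matrix up the spatial hierarchy
#'
#' Sums abundances of all samples that map to the same unit at the requested
#' scale (plot, depth stratum, lake or region). Summation — rather than
#' averaging — conserves total abundance exactly, matching the aggregation
#' of quadrats into plots in the field design.
#'
#' @param comm Community data at plot grain (rows are plots).
#' @param hier Spatial hierarchy (see [validate_hierarchy()]).
#' @param scale One of `"plot"`, `"depth"`, `"lake"`, `"region"`.
#' @return Abundance matrix with one row per unit at `scale`.
#' @export
pool_to_scale <- function(comm, hier, scale = c("plot", "depth", "lake", "region")) {
  scale <- match.arg(scale)
  m <- as_community_matrix(comm)
  hier <- validate_hierarchy(hier)
  missing <- setdiff(rownames(m), as.character(hier$plot))
  if (length(missing)) {
    stop("sample(s) missing from hierarchy: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  key_col <- switch(scale, plot = "plot", depth = "depth_stratum",
                    lake = "lake", region = "region")
  key <- hier[[key_col]][match(rownames(m), as.character(hier$plot))]
  rowsum(m, group = as.character(key), reorder = FALSE)
}

#' Per-sample species richness
#'
#' Number of species with positive abundance in each sample, with a summary
#' (min, median, max) attached as the `summary` attribute.
#'
#' @param comm Community data.
#' @return Tibble with columns `sample`, `richness`.
#' @export
richness_profile <- function(comm) {
  m <- as_community_matrix(comm, drop_empty = FALSE)
  r <- rowSums(m > 0)
  out <- tibble::tibble(sample = rownames(m), richness = as.integer(r))
  attr(out, "summary") <- c(min = min(r), median = stats::median(r), max = max(r))
  out
}
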