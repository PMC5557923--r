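#' Read a trait table with its trait-kind declarations
#'
#' @param path CSV with a `species` column and one column per trait.
#' @param config Optional YAML path (or pre-parsed list) declaring trait
#'   kinds and units, as `traits: {name: {type: continuous, units: cm}}`.
#'   Without it, numeric columns are treated as continuous.
#' @return Validated trait tibble with `trait_types` / `trait_units`
#'   attributes.
#' @export
read_trait_table <- function(path, config = NULL) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  types <- NULL
  if (!is.null(config)) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    decl <- config$traits
    types <- vapply(decl, function(d) d$type, character(1))
    units <- vapply(decl, function(d) d$units %||% "", character(1))
    attr(tr, "trait_units") <- units
  }
  validate_trait_table(tr, types)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a community abundance matrix (samples x species CSV)
#' @param path CSV whose first column holds sample labels.
#' @return Abundance matrix (see [as_community_matrix()]).
#' @export
read_community <- function(path) {
  as_community_matrix(readr::read_csv(path, show_col_types = FALSE))
}

#' Read and validate a spatial hierarchy CSV
#' @param path CSV with columns plot, depth_stratum, water_depth_m, lake,
#'   region, elevation_m.
#' @return Validated hierarchy tibble.
#' @export
read_hierarchy <- function(path) {
  validate_hierarchy(readr::read_csv(path, show_col_types = FALSE))
}

#' Read a per-lake environment table CSV
#' @param path CSV with a `lake` column plus parameter columns.
#' @return Tibble.
#' @export
read_environment <- function(path) {
  env <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot("lake" %in% names(env))
  env
}

#' Write a square distance matrix as CSV
#' @param d Distance matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dist_csv <- function(d, path) {
  d <- as.matrix(d)
  out <- dplyr::bind_cols(tibble::tibble(species = rownames(d)),
                          tibble::as_tibble(d))
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a synthetic survey to CSV files plus a ground-truth YAML
#'
#' Writes `traits.csv`, `communities.csv`, `hierarchy.csv`,
#' `environment.csv` and `ground_truth.yaml` into `dir`.
#'
#' @param survey List from [generate_survey()].
#' @param traits Trait table from [generate_traits()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, traits, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(traits, file.path(dir, "traits.csv"))
  comm <- dplyr::bind_cols(
    tibble::tibble(sample = rownames(survey$community)),
    tibble::as_tibble(survey$community)
  )
  readr::write_csv(comm, file.path(dir, "communities.csv"))
  readr::write_csv(survey$hier, file.path(dir, "hierarchy.csv"))
  readr::write_csv(survey$env, file.path(dir, "environment.csv"))
  scen <- survey$ground_truth$scenario
  yaml::write_yaml(
    list(
      scenario = lapply(unclass(scen), function(x) {
        if (is.null(names(x))) unname(x) else as.list(x)
      }),
      trait_types = as.list(attr(traits, "trait_types"))
    ),
    file.path(dir, "ground_truth.yaml")
  )
  invisible(dir)
}
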