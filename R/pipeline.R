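#' Run the full dispersion analysis end-to-end
#'
#' Orchestrates every stage on one configuration: load (or simulate) the
#' survey, build the six trait dendrograms, compute observed and null
#' dispersion at the requested scales, standardize into SES, summarise
#' group-level departure with Wilcoxon signed-rank tests, partition
#' plot-grain alpha SES variance over the hierarchy, and fit the
#' scale-specific gradient trends. All tables are returned and, when
#' `output_dir` is set, written as CSV together with a machine-readable run
#' manifest.
#'
#' @param config A YAML path or a list with fields:
#'   \describe{
#'     \item{seed}{integer, mandatory.}
#'     \item{n_iter}{null iterations, >= 99 (default 999).}
#'     \item{scales}{subset of plot/depth/lake/region (default all).}
#'     \item{metrics}{subset of PW/NN/Dpw/Dnn (default all).}
#'     \item{input}{list of paths `traits`, `traits_config`, `community`,
#'       `hierarchy`, `environment`; or}
#'     \item{simulate}{list of [scenario()] arguments (seed defaults to the
#'       run seed) used instead of `input`.}
#'     \item{output_dir}{optional directory for CSV outputs.}
#'   }
#' @return List of tibbles: `ses`, `departure`, `varcomp`, `trends`,
#'   `richness`, plus `dendrograms` and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  seed <- as.integer(config$seed)
  n_iter <- as.integer(config$n_iter %||% 999)
  if (n_iter < 99) stop("n_iter must be at least 99", call. = FALSE)
  scales <- config$scales %||% c("plot", "depth", "lake", "region")
  metrics <- config$metrics %||% c("PW", "NN", "Dpw", "Dnn")

  log_stage <- function(...) message("[fundisp] ", ...)

  if (!is.null(config$simulate)) {
    log_stage("simulating survey")
    args <- config$simulate
    args$seed <- as.integer(args$seed %||% seed)
    scen <- do.call(scenario, args)
    traits <- generate_traits(scen)
    survey <- generate_survey(scen, traits)
    comm <- survey$community; hier <- survey$hier; env <- survey$env
  } else if (!is.null(config$input)) {
    log_stage("reading inputs")
    inp <- config$input
    for (f in c("traits", "community", "hierarchy")) {
      if (is.null(inp[[f]])) stop("config$input$", f, " is required", call. = FALSE)
      if (!file.exists(inp[[f]])) stop("missing file: ", inp[[f]], call. = FALSE)
    }
    traits <- read_trait_table(inp$traits, inp$traits_config)
    comm <- read_community(inp$community)
    hier <- read_hierarchy(inp$hierarchy)
    env <- if (!is.null(inp$environment)) read_environment(inp$environment) else NULL
  } else {
    stop("config needs either $input or $simulate", call. = FALSE)
  }

  log_stage("building trait dendrograms")
  dendros <- withCallingHandlers(
    build_all_dendrograms(traits),
    warning = function(w) invokeRestart("muffleWarning")
  )

  log_stage("dispersion + null models (", n_iter, " iterations)")
  ses_tbl <- ses_dispersion(comm, hier, dendros, scales = scales,
                            metrics = metrics, n_iter = n_iter, seed = seed)

  log_stage("group-level departure tests")
  departure <- summarize_departure(ses_tbl)

  varcomp <- NULL
  if ("plot" %in% scales && any(c("PW", "NN") %in% metrics)) {
    log_stage("variance components")
    varcomp <- ses_tbl |>
      dplyr::filter(.data$scale == "plot",
                    .data$metric %in% c("PW", "NN"), .data$defined) |>
      dplyr::rename(plot = "unit") |>
      dplyr::group_by(.data$trait_metric, .data$metric) |>
      dplyr::group_modify(function(d, key) {
        vc <- try(variance_partition(d, hier), silent = TRUE)
        if (inherits(vc, "try-error")) {
          tibble::tibble(level = character(0), variance = numeric(0),
                         share_pct = numeric(0))
        } else tibble::as_tibble(vc)
      }) |>
      dplyr::ungroup()
  }

  log_stage("gradient trends")
  trend_scales <- intersect(c("depth", "lake", "region"), scales)
  trends <- dplyr::bind_rows(lapply(trend_scales, function(sc) {
    if (sc == "lake" && is.null(env)) return(NULL)
    scale_gradient_trends(ses_tbl, hier, env, scale = sc)
  }))

  rich <- richness_profile(comm)

  manifest <- list(
    package = "fundisp",
    version = as.character(utils::packageVersion("fundisp")),
    seed = seed, n_iter = n_iter,
    scales = scales, metrics = metrics,
    n_plots = nrow(comm), n_species = ncol(comm),
    n_lakes = length(unique(hier$lake)),
    n_regions = length(unique(hier$region)),
    richness = as.list(attr(rich, "summary"))
  )

  if (!is.null(config$output_dir)) {
    out <- config$output_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(ses_tbl, file.path(out, "ses.csv"))
    readr::write_csv(departure, file.path(out, "departure.csv"))
    if (!is.null(varcomp)) readr::write_csv(varcomp, file.path(out, "varcomp.csv"))
    if (nrow(trends)) readr::write_csv(trends, file.path(out, "trends.csv"))
    for (nm in names(dendros)) {
      write_newick(dendros[[nm]], file.path(out, paste0("dendrogram_", nm, ".nwk")))
    }
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(ses = ses_tbl, departure = departure, varcomp = varcomp,
       trends = trends, richness = rich, dendrograms = dendros,
       manifest = manifest)
}
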