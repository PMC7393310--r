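pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage:", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

md5_of_object <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 15,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Normalize a pipeline configuration
#'
#' Accepts a YAML file path or a nested list with (all optional) entries
#' `simulation` (arguments of [simulation_config()]), `sampler` (arguments
#' of [sampler_config()]), `priors` (arguments of [prior_config()]),
#' `indices` (subset of [SB_INDICES]) and `household_rule`.
#'
#' @param config Path to a YAML file, or a list.
#' @return Validated configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  indices <- config$indices
  if (is.null(indices)) indices <- SB_INDICES
  bad <- setdiff(indices, SB_INDICES)
  if (length(bad) > 0) {
    stop("unknown social index in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sim <- do.call(simulation_config, as.list(config$simulation))
  smp <- do.call(sampler_config, as.list(config$sampler))
  pri <- do.call(prior_config, as.list(config$priors))
  list(simulation = sim, sampler = smp, priors = pri, indices = indices,
       household_rule = if (is.null(config$household_rule)) "alone"
       else config$household_rule)
}

#' Run the full pipeline: simulate, prepare, fit, report
#'
#' Generates (or loads) a cohort, then for each requested social index
#' builds the design, samples the posterior and writes a summary CSV with
#' posterior means and 95% HPDIs for all region, network and confound
#' coefficients. All randomness is derived from the configured seeds, so
#' re-running with an identical configuration reproduces byte-identical
#' CSV outputs. A `manifest.json` records the configuration hash, seeds
#' and output digests.
#'
#' @param config Configuration accepted by [pipeline_config()].
#' @param out_dir Output directory (created).
#' @param atlas Atlas used throughout (default: packaged).
#' @param phenotypes_csv,volumes_csv Optional paths to existing cohort
#'   tables; when supplied, the simulation stage is skipped and these are
#'   used instead.
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(config = list(), out_dir, atlas = load_atlas("default"),
                         phenotypes_csv = NULL, volumes_csv = NULL) {
  cfg <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  if (is.null(phenotypes_csv) || is.null(volumes_csv)) {
    cohort <- pipeline_stage("simulate",
                             generate_cohort(cfg$simulation, atlas))
    records <- cohort$records
    volumes <- cohort$volumes
    paths <- pipeline_stage("simulate", write_cohort(cohort, out_dir))
    files <- c(files, paths)
  } else {
    records <- pipeline_stage("load", read_phenotypes(phenotypes_csv))
    volumes <- pipeline_stage("load", read_region_volumes(volumes_csv))
  }

  summaries <- list()
  for (index in cfg$indices) {
    design <- pipeline_stage(
      paste0("prepare:", index),
      build_design(volumes, records, index, atlas = atlas,
                   household_rule = cfg$household_rule, quiet = TRUE))
    sampler <- cfg$sampler
    sampler$seed <- cfg$sampler$seed + match(index, SB_INDICES) - 1L
    draws <- pipeline_stage(paste0("fit:", index),
                            sample_posterior(design, cfg$priors, sampler))
    summ <- pipeline_stage(paste0("report:", index),
                           summarize_posterior(draws))
    out_csv <- file.path(out_dir, paste0("summary_", index, ".csv"))
    utils::write.csv(summ, out_csv, row.names = FALSE)
    files <- c(files, stats::setNames(out_csv, paste0("summary_", index)))
    summaries[[index]] <- summ
  }

  manifest <- list(
    package = "sbhbm",
    version = as.character(utils::packageVersion("sbhbm")),
    created = format(Sys.time(), tz = "UTC"),
    config_hash = md5_of_object(
      cfg[c("simulation", "sampler", "priors", "indices",
            "household_rule")]),
    seeds = list(simulation = cfg$simulation$seed,
                 sampler = cfg$sampler$seed),
    indices = cfg$indices,
    atlas_source = attr(atlas, "source"),
    file_digests = as.list(tools::md5sum(unname(files))))
  manifest_path <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             manifest_path)
  files <- c(files, manifest = manifest_path)
  invisible(as.list(files))
}

#' Per-network report: interval plot plus table slice
#'
#' Presentational view of one network's region-by-group posterior
#' coefficients (association of z-scored region volume with z-scored age):
#' the table slice of the summary, and a point-interval plot built from
#' exactly those numbers.
#'
#' @param summary Data frame from [summarize_posterior()].
#' @param network One of [SB_NETWORKS].
#' @return List with `table` (summary rows of the network's region
#'   coefficients) and `plot` (a ggplot object).
#' @export
render_network_report <- function(summary, network) {
  if (!network %in% SB_NETWORKS) {
    stop("unknown network: ", network, call. = FALSE)
  }
  slice <- summary[summary$parameter_type == "region_beta" &
                     summary$network == network, , drop = FALSE]
  if (nrow(slice) == 0L) {
    stop("summary contains no region coefficients for network '",
         network, "'", call. = FALSE)
  }
  plt <- ggplot2::ggplot(
    slice,
    ggplot2::aes(x = .data$posterior_mean, y = .data$region,
                 xmin = .data$hpdi_lower, xmax = .data$hpdi_upper,
                 color = .data$group)) +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(0.6)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      title = paste0(network, " network"),
      x = "association with z-scored age (posterior mean, 95% HPDI)",
      y = NULL, color = "group") +
    ggplot2::theme_minimal()
  list(table = slice, plot = plt)
}
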