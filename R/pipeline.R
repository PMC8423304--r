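#' End-to-end pipeline orchestration
#'
#' [enm_pipeline()] runs the whole workflow on in-memory objects:
#' block-wise PCA reduction of the current stack, projection of the fitted
#' transforms onto the future stacks, occurrence thinning, the jackknife
#' ensemble validation, per-scenario consensus maps, and scenario area
#' comparison. [run_pipeline()] wraps it with file I/O driven by a
#' validated configuration (YAML or list) and writes all products plus a
#' manifest to an output directory. A single global seed deterministically
#' derives every stage seed, so a rerun with the same configuration
#' reproduces every numeric output.
#'
#' @name cli_config
NULL

#' Default run configuration
#'
#' @return nested list of configuration defaults: the nine-family
#'   ensemble, 10 PA sets x 10 runs, 6 climate + 2 edaphic PCA axes
#'   (either may be set to `"broken_stick"`), disk PA bounds from the
#'   presences, majority consensus, exact Poisson-binomial test at
#'   alpha = 0.05
#' @export
default_config <- function() {
  list(
    families = LEARNER_FAMILIES,
    n_runs = 10,
    pa = list(n_sets = 10, d_min_km = NULL, d_max_km = NULL),
    pca = list(climate = list(n_axes = 6), edaphic = list(n_axes = 2)),
    consensus = list(rule = "majority"),
    test = "poisson_binomial",
    alpha = 0.05,
    seed = 1,
    hyper = list(),
    blocks = NULL,
    paths = NULL
  )
}

# deep-merge user settings onto defaults, rejecting unknown keys
merge_config <- function(user, defaults = default_config(), path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(user[[k]]) && !(k %in% c("hyper", "paths", "blocks"))) {
      defaults[[k]] <- merge_config(user[[k]], defaults[[k]],
                                    paste0(path, ".", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read and validate a run configuration
#'
#' @param config a YAML file path or a named list of overrides; unknown
#'   keys are rejected
#' @return validated configuration list (class `run_config`)
#' @export
read_run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config)
  cfg$families <- toupper(unlist(cfg$families))
  stopifnot(length(cfg$families) >= 1, cfg$n_runs >= 1, cfg$pa$n_sets >= 1)
  for (f in cfg$families) get_learner(f)  # errors on unregistered family
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("run_config", "list")
  cfg
}

# split a stack's layers into climate / edaphic blocks
split_blocks <- function(stack, blocks = NULL) {
  nms <- names(stack$layers)
  if (is.null(blocks)) {
    clim <- grep("^(bio|clim)", nms, value = TRUE)
    eda <- setdiff(nms, clim)
  } else {
    clim <- intersect(blocks$climate, nms)
    eda <- intersect(blocks$edaphic, nms)
  }
  if (length(clim) < 2) stop("climate block needs >= 2 layers")
  list(climate = clim, edaphic = eda)
}

subset_stack <- function(stack, layer_names) {
  env_stack(stack$layers[layer_names], stack$grid, stack$scenario)
}

#' Run the full ensemble niche-modelling workflow in memory
#'
#' @param current current-scenario [env_stack()]
#' @param futures named list of future-scenario [env_stack()]s (same
#'   variables and grid); may be empty
#' @param occ an `occurrence_set` (raw records are thinned to the grid)
#' @param config a validated configuration from [read_run_config()]
#' @param polygons optional [polygon_set()] for overlap accounting
#' @return list with `report` (the [jackknife_run()] result), `consensus`
#'   (per scenario: consensus `binary_map`, frequency matrix,
#'   n_contributing), `comparison` (a `scenario_comparison`), `overlaps`
#'   (per-scenario polygon tables or NULL), `pca` (fitted transforms),
#'   `occ` (the thinned occurrences) and `config`
#' @export
enm_pipeline <- function(current, futures = list(), occ,
                         config = read_run_config(), polygons = NULL) {
  blocks <- split_blocks(current, config$blocks)
  clim_fit <- fit_pca(subset_stack(current, blocks$climate),
                      n_axes = config$pca$climate$n_axes,
                      block_label = "climate", score_prefix = "climPC")
  has_eda <- length(blocks$edaphic) >= 2
  eda_fit <- if (has_eda)
    fit_pca(subset_stack(current, blocks$edaphic),
            n_axes = config$pca$edaphic$n_axes,
            block_label = "edaphic_topographic", score_prefix = "edaPC")
  score_of <- function(stack) {
    parts <- list(project_transform(clim_fit$transform,
                                    subset_stack(stack, blocks$climate)))
    if (has_eda)
      parts <- c(parts, list(project_transform(eda_fit$transform,
                                               subset_stack(stack, blocks$edaphic))))
    combine_stacks(parts)
  }
  score_stacks <- c(list(current = score_of(current)),
                    lapply(futures, score_of))
  if (!isTRUE(occ$thinned)) occ <- thin_to_cells(occ, current$grid)
  report <- jackknife_run(occ, score_stacks, config)
  if (report$D == 0) {
    warning("no replicate predicted its withheld presence; ",
            "consensus maps and area comparison are unavailable")
    cons <- NULL
    comparison <- NULL
  } else {
    cons <- lapply(names(score_stacks), function(sc)
      consensus(report$binary_maps[[sc]], report$replicates$success,
                rule = config$consensus$rule))
    names(cons) <- names(score_stacks)
    comparison <- change_stats(cons$current$consensus,
                               lapply(cons[-1], `[[`, "consensus"))
  }
  overlaps <- if (!is.null(polygons) && !is.null(cons))
    lapply(cons, function(x) overlap_with_polygons(x$consensus, polygons))
  list(report = report, consensus = cons, comparison = comparison,
       overlaps = overlaps, occ = occ,
       pca = list(climate = clim_fit$transform,
                  edaphic = if (has_eda) eda_fit$transform),
       config = config)
}

#' Run the pipeline from a configuration file and write all outputs
#'
#' The configuration's `paths` entry must name `current` (vector of .asc
#' rasters or a directory of them), optionally `futures` (named list of
#' the same), `occurrences` (CSV), optionally `polygons` (GeoJSON), and
#' `output_dir`. Products written: per-scenario consensus and frequency
#' rasters, the jackknife report (CSV + JSON), the scenario comparison
#' (CSV + JSON), polygon overlaps (CSV), and `manifest.json` recording
#' the configuration, seed and package version.
#'
#' @param config YAML path or configuration list (see [read_run_config()])
#' @return the [enm_pipeline()] result, invisibly
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  p <- cfg$paths
  if (is.null(p$current) || is.null(p$occurrences) || is.null(p$output_dir))
    stop("config$paths must name 'current', 'occurrences' and 'output_dir'")
  expand <- function(x) if (length(x) == 1 && dir.exists(x))
    list.files(x, pattern = "\\.asc$", full.names = TRUE) else x
  for (f in c(expand(p$current), unlist(lapply(p$futures, expand)),
              p$occurrences, p$polygons))
    if (!file.exists(f)) stop("missing input path: ", f)
  current <- read_stack(expand(p$current), "current")
  futures <- lapply(p$futures, function(ps) read_stack(expand(ps), "future"))
  if (length(futures)) names(futures) <- names(p$futures)
  occ <- load_records(p$occurrences)
  polygons <- if (!is.null(p$polygons)) read_geojson(p$polygons)
  res <- enm_pipeline(current, futures, occ, cfg, polygons)
  out <- p$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  for (sc in names(res$consensus)) {
    write_asc(res$consensus[[sc]]$consensus$values, current$grid,
              file.path(out, paste0("consensus_", sc, ".asc")))
    write_asc(res$consensus[[sc]]$frequency, current$grid,
              file.path(out, paste0("frequency_", sc, ".asc")))
  }
  write_jackknife_report(res$report,
                         csv_path = file.path(out, "jackknife.csv"),
                         json_path = file.path(out, "jackknife.json"))
  if (!is.null(res$comparison)) {
    utils::write.csv(res$comparison, file.path(out, "comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(res$comparison, file.path(out, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (!is.null(res$overlaps))
    utils::write.csv(
      do.call(rbind, lapply(names(res$overlaps), function(sc)
        cbind(scenario = sc, res$overlaps[[sc]]))),
      file.path(out, "overlaps.csv"), row.names = FALSE)
  manifest <- list(
    package = "nichecast",
    version = as.character(utils::packageVersion("nichecast")),
    seed = cfg$seed,
    n_replicates = res$report$n,
    n_models_per_replicate = length(cfg$families) * cfg$pa$n_sets * cfg$n_runs,
    config = cfg[setdiff(names(cfg), "paths")],
    paths = p)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, null = "null")
  invisible(res)
}

#' Emit a complete synthetic run directory
#'
#' Writes a ready-to-run virtual-species study: current and two
#' future-scenario raster stacks, an occurrences CSV, a truth JSON (the
#' species, latent shifts and true suitable areas) and a matching run
#' configuration YAML.
#'
#' @param dir output directory
#' @param seed global seed
#' @param n_rows,n_cols grid size
#' @param n_presences presence records to sample
#' @param losses named numeric vector of target true fractional area
#'   losses for the future scenarios
#' @param weights,intercept virtual-species definition (defaults: a strong
#'   species on the first two latent factors)
#' @return invisibly, the path of the written config YAML
#' @export
simulate_run_dir <- function(dir, seed = 1, n_rows = 60, n_cols = 60,
                             n_presences = 7,
                             losses = c(ssp245 = 0.3, ssp585 = 0.8),
                             weights = c(3, 1.5, 0, 0), intercept = -1) {
  venv <- generate_env(n_rows = n_rows, n_cols = n_cols,
                       latent_dim = length(weights), seed = seed)
  species <- virtual_species_spec(weights, intercept)
  occ <- sample_presences(species, venv, n_presences,
                          seed = derive_seed(seed, 7))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(venv, file.path(dir, "current"))
  truth <- list(weights = weights, intercept = intercept, seed = seed,
                true_area_current_km2 = true_suitable_area(species, venv),
                scenarios = list())
  fut_paths <- list()
  for (nm in names(losses)) {
    sh <- shift_for_loss(species, venv, losses[[nm]], label = nm)
    fut <- apply_shift(venv, sh)
    write_stack(fut, file.path(dir, nm))
    fut_paths[[nm]] <- file.path(dir, nm)
    truth$scenarios[[nm]] <- list(
      target_loss = losses[[nm]],
      latent_delta = sh$latent_delta,
      true_area_km2 = true_suitable_area(species, fut))
  }
  utils::write.csv(occ$records, file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- list(seed = seed,
              paths = list(current = file.path(dir, "current"),
                           futures = fut_paths,
                           occurrences = file.path(dir, "occurrences.csv"),
                           output_dir = file.path(dir, "output")))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(file.path(dir, "config.yaml"))
}
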