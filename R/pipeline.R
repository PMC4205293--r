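#' Default pipeline configuration
#'
#' All-synthetic configuration running every stage end to end.  Any element
#' can be overridden through \code{\link{run_pipeline}}'s \code{config}
#' argument (an R list or a YAML file with the same structure).
#'
#' @return nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "paleodemog_run",
    synthetic = list(
      study = list(truth_scenario = "Expansion_6_0", inbreeding = 0.21,
                   n_loci = 11L),
      map = list(grid_shape = c(60L, 60L), planted_dynamic = "Expansion")
    ),
    genotypes = NULL,    # CSV path; used instead of the synthetic study
    coords = NULL,       # CSV path (pop_id, lon, lat)
    maps_manifest = NULL, # manifest.csv path; used instead of synthetic maps
    scenarios = scenario_names(),
    replicates = 2000L,
    permutations = 999L,
    suitability_threshold = 0.3,
    range_cutoff = 199,
    mutation_rate = 0.01,
    generation_time = 12,
    taus = c(0.1, 0.5, 0.9)
  )
}

# deterministic per-stage substream: stage insertion does not perturb other
# stages' draws
.stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(master) %% 50021 * 69621 + h) %% 2147483563L)
}

.load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  merge_lists <- function(a, b) {
    for (nm in names(b))
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_lists(a[[nm]], b[[nm]]) else b[[nm]]
    a
  }
  cfg <- merge_lists(base, config)
  if (is.null(cfg$seed)) stop("config field 'seed' is required")
  if (is.null(cfg$genotypes) && is.null(cfg$synthetic$study))
    stop("config must provide either 'genotypes' (CSV path) or a 'synthetic$study' spec")
  if (is.null(cfg$maps_manifest) && is.null(cfg$synthetic$map))
    stop("config must provide either 'maps_manifest' or a 'synthetic$map' spec")
  for (f in c("genotypes", "coords", "maps_manifest"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config field '", f, "' points to a missing file: ", cfg[[f]])
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end from a single configuration: input
#' generation or loading, per-population genetic summaries, simulation-based
#' multi-model comparison, suitability-ensemble post-processing (consensus,
#' refugium, range-dynamics classification, variance partition), and the
#' spatial-genetics report.  All tables are written as CSV, maps as ESRI
#' ASCII grids, and a JSON manifest records versions, seeds and input
#' digests.  Identical configurations and seeds give identical outputs.
#'
#' @param config an R list (see \code{\link{default_pipeline_config}}) or
#'   the path to a YAML file with the same structure.
#' @return invisibly, a list with the main results and output paths.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- .load_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  ## inputs ----------------------------------------------------------------
  if (is.null(cfg$genotypes)) {
    spec_args <- cfg$synthetic$study
    spec_args$seed <- .stage_seed(cfg$seed, "genotypes")
    spec <- do.call(synthetic_study_spec, spec_args)
    gd <- gen_observed_dataset(spec)
    paths$genotypes <- file.path(cfg$out_dir, "genotypes.csv")
    write_genotypes_csv(gd, paths$genotypes)
    write_genepop(gd, file.path(cfg$out_dir, "genotypes.gen"))
  } else {
    gd <- read_genotypes_csv(cfg$genotypes)
  }
  if (is.null(cfg$maps_manifest)) {
    map_args <- cfg$synthetic$map
    map_args$seed <- .stage_seed(cfg$seed, "maps")
    mspec <- do.call(synthetic_map_spec, map_args)
    stack <- gen_suitability_stack(mspec)
    paths$maps <- write_stack(stack, file.path(cfg$out_dir, "maps"))
  } else {
    stack <- read_stack(cfg$maps_manifest)
  }
  if (is.null(cfg$coords)) {
    # sample coordinates inside the map extent so extraction never misses
    g <- stack$grid
    ext <- c(g$xll, g$yll, g$xll + g$ncol * g$cellsize,
             g$yll + g$nrow * g$cellsize)
    coords <- gen_population_coords(length(unique(gd$pop)), extent = ext,
                                    seed = .stage_seed(cfg$seed, "coords"))
    coords$pop_id <- as.character(unique(gd$pop))
    paths$coords <- file.path(cfg$out_dir, "coords.csv")
    utils::write.csv(coords, paths$coords, row.names = FALSE)
  } else {
    coords <- utils::read.csv(cfg$coords, stringsAsFactors = FALSE)
  }

  ## genetic summaries -----------------------------------------------------
  set.seed(.stage_seed(cfg$seed, "stats"))
  summ <- summarise_populations(gd)
  paths$summary <- file.path(cfg$out_dir, "summary_stats.csv")
  utils::write.csv(as.data.frame(summ), paths$summary, row.names = FALSE)
  observed_he <- summ$He[summ$pop == "Mean"]

  ## model selection -------------------------------------------------------
  sizes <- as.integer(table(gd$pop)[as.character(unique(gd$pop))] /
                        length(unique(gd$locus)))
  cmp_cfg <- simulation_config(sizes, n_loci = length(unique(gd$locus)),
                               mutation_rate = cfg$mutation_rate)
  cmp <- rank_models(observed_he, cfg$scenarios, cmp_cfg,
                     R = cfg$replicates,
                     seed = .stage_seed(cfg$seed, "model_selection"),
                     n_demes = length(unique(gd$pop)))
  paths$model_selection <- file.path(cfg$out_dir, "model_selection.csv")
  utils::write.csv(as.data.frame(cmp), paths$model_selection,
                   row.names = FALSE)

  ## map post-processing ---------------------------------------------------
  periods <- unique(stack$layers$period)
  cons <- lapply(periods, consensus_map, stack = stack)
  names(cons) <- periods
  for (p in periods) {
    fp <- file.path(cfg$out_dir, paste0("consensus_", p, ".asc"))
    write_ascii_grid(cons[[p]], fp)
    paths[[paste0("consensus_", p)]] <- fp
  }
  ref <- refugium_map(cons, threshold = cfg$suitability_threshold)
  paths$refugium <- file.path(cfg$out_dir, "refugium.asc")
  write_ascii_grid(ref, paths$refugium)
  dyn <- classify_stack_dynamics(stack, threshold = cfg$suitability_threshold,
                                 cutoff = cfg$range_cutoff)
  paths$dynamics <- file.path(cfg$out_dir, "range_dynamics.csv")
  utils::write.csv(dyn, paths$dynamics, row.names = FALSE)
  vp <- variance_partition(stack)
  paths$variance <- file.path(cfg$out_dir, "variance_partition.csv")
  utils::write.csv(data.frame(component = names(vp$overall),
                              proportion_ss = unname(vp$overall)),
                   paths$variance, row.names = FALSE)

  ## spatial genetics ------------------------------------------------------
  fst <- pairwise_fst_matrix(gd, linearize = TRUE)
  gdist <- geo_distance_matrix(coords)[rownames(fst), rownames(fst)]
  mant <- mantel_test(log(gdist + diag(nrow(gdist))), fst,
                      n_perm = cfg$permutations,
                      seed = .stage_seed(cfg$seed, "mantel"))
  geo <- population_geo(summ, coords, stack,
                        threshold = cfg$suitability_threshold)
  env <- envelope_report(geo, taus = cfg$taus,
                         seed = .stage_seed(cfg$seed, "quantreg"))
  paths$spatial <- file.path(cfg$out_dir, "spatial_regressions.csv")
  utils::write.csv(env, paths$spatial, row.names = FALSE)
  paths$mantel <- file.path(cfg$out_dir, "mantel.csv")
  utils::write.csv(data.frame(r = mant$r, r2 = mant$r2, p = mant$p,
                              n_perm = mant$n_perm),
                   paths$mantel, row.names = FALSE)

  ## manifest --------------------------------------------------------------
  files <- unlist(paths[vapply(paths, is.character, logical(1))])
  files <- files[file.exists(files)]
  manifest <- list(
    package = "paleodemog",
    version = as.character(utils::packageVersion("paleodemog")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    files = as.list(tools::md5sum(files)))
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             paths$manifest)

  invisible(list(summary = summ, model_selection = cmp, dynamics = dyn,
                 variance = vp$overall, mantel = mant, envelope = env,
                 paths = paths))
}
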