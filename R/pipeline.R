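#' Run a configured multi-stage experiment
#'
#' Orchestrates the pipeline stages in dependency order
#' (\code{synth_labels} -> \code{simulate} -> \code{voids} -> \code{fit} ->
#' \code{compare}; \code{synth_clones} -> \code{cluster} -> \code{filter} ->
#' \code{tree} -> \code{territory}), writes every stage's outputs under the
#' output directory and emits a \code{manifest.json} echoing the fully
#' resolved configuration, per-stage seeds and output paths. Stage seeds are
#' derived from the single global seed as \code{seed + 1000 * stage-offset}
#' (offsets: synth_labels 1, simulate 2, synth_clones 3, cluster 4), so
#' deterministic outputs are byte-identical on rerun.
#'
#' @param config a named list, or a path to a YAML/JSON configuration file.
#'   Recognised top-level keys: \code{stages} (character vector), \code{seed}
#'   (integer), \code{output_dir}, plus one optional parameter block per
#'   stage. Unknown keys are rejected.
#' @param outputDir overrides \code{config$output_dir}.
#' @return The manifest, invisibly (a named list; also written as JSON).
#' @examples
#' cfg <- list(stages = "synth_labels", seed = 1,
#'             synth_labels = list(nRows = 16, nCols = 16, fraction = 0.4))
#' m <- runExperiment(cfg, outputDir = tempfile())
#' @export
runExperiment <- function(config, outputDir = NULL) {
  config <- .loadConfig(config)
  config <- .resolveConfig(config)
  if (!is.null(outputDir)) config$output_dir <- outputDir
  if (is.null(config$output_dir))
    stop("an output directory is required (config$output_dir or outputDir)",
         call. = FALSE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  state <- new.env(parent = emptyenv())
  outputs <- list()
  for (stage in config$stages) {
    res <- .runStage(stage, config, state)
    outputs[[stage]] <- res
  }

  manifest <- list(package = "basalClones",
                   version = as.character(utils::packageVersion("basalClones")),
                   config = config[setdiff(names(config), "output_dir")],
                   output_dir = config$output_dir,
                   stage_seeds = .stageSeeds(config$seed),
                   outputs = outputs)
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

.STAGES <- c("synth_labels", "simulate", "voids", "fit", "compare",
             "synth_clones", "cluster", "filter", "tree", "territory")
.STAGE_SEED_OFFSET <- c(synth_labels = 1L, simulate = 2L, synth_clones = 3L,
                        cluster = 4L)

.stageSeeds <- function(seed) {
  if (is.null(seed)) return(NULL)
  as.list(seed + 1000L * .STAGE_SEED_OFFSET)
}

.configError <- function(...) {
  stop(errorCondition(paste0(...), class = c("bc_config_error", "error")))
}

.dependencyError <- function(stage, what) {
  stop(errorCondition(
    sprintf("stage '%s' needs %s: run the producing stage first or give an input path",
            stage, what),
    class = c("bc_dependency_error", "error")))
}

.loadConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) .configError("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) .configError("config must be a list or a file path")
  config
}

.resolveConfig <- function(config) {
  known <- c("name", "stages", "seed", "output_dir", .STAGES)
  extra <- setdiff(names(config), known)
  if (length(extra))
    .configError("unknown config key(s): ", paste(extra, collapse = ", "))
  config$stages <- as.character(config$stages %||% character(0))
  badStage <- setdiff(config$stages, .STAGES)
  if (length(badStage))
    .configError("unknown stage(s): ", paste(badStage, collapse = ", "))
  if (is.null(config$seed)) config$seed <- 1L
  config
}

.stageParams <- function(config, stage, defaults) {
  p <- config[[stage]] %||% list()
  extra <- setdiff(names(p), names(defaults))
  if (length(extra))
    .configError(sprintf("unknown key(s) in stage '%s': %s", stage,
                         paste(extra, collapse = ", ")))
  utils::modifyList(defaults, p)
}

.runStage <- function(stage, config, state) {
  out <- config$output_dir
  seeds <- .stageSeeds(config$seed)
  switch(stage,
    synth_labels = {
      p <- .stageParams(config, stage, list(
        nRows = 128, nCols = 128, fraction = 0.5, cloneSeedSize = 1,
        boundary = "periodic-both"))
      g <- generateLabelField(p$nRows, p$nCols, p$fraction, p$cloneSeedSize,
                              seed = seeds$synth_labels,
                              boundary = p$boundary)
      state$field <- g$field
      path <- file.path(out, "field.csv")
      writeLabelField(g$field, path)
      list(field = path, realized_fraction = g$realizedFraction)
    },
    simulate = {
      p <- .stageParams(config, stage, list(
        field = NULL, nSweeps = 100, snapshots = NULL, neighborhood = 4,
        mode = "neutral", fitterFraction = 0, selection = Inf,
        boundary = "periodic-both"))
      f <- if (!is.null(p$field)) readLabelField(p$field, p$boundary)
      else state$field
      if (is.null(f)) .dependencyError(stage, "a label field (synth_labels)")
      set.seed(seeds$simulate)
      if (p$fitterFraction > 0) f <- seedGenotypes(f, p$fitterFraction)
      snaps <- p$snapshots %||% p$nSweeps
      traj <- runSimulation(f, p$nSweeps, snapshotSweeps = snaps,
                            neighborhood = p$neighborhood, mode = p$mode,
                            selection = p$selection)
      paths <- vapply(traj, function(x) {
        fp <- file.path(out, sprintf("field_sweep%s.csv", fieldTime(x)))
        writeLabelField(x, fp)
        fp
      }, character(1))
      state$field <- traj[[length(traj)]]
      list(snapshots = unname(paths))
    },
    voids = {
      p <- .stageParams(config, stage, list(
        field = NULL, connectivity = 4, minSize = 2,
        boundary = "periodic-both"))
      f <- if (!is.null(p$field)) readLabelField(p$field, p$boundary)
      else state$field
      if (is.null(f)) .dependencyError(stage, "a label field (simulate)")
      vd <- findVoids(f, p$connectivity, p$minSize)
      state$voids <- vd
      path <- file.path(out, "voids.tsv")
      writeExceedance(vd, path)
      list(curve = path, n_voids = length(voidSizes(vd)))
    },
    fit = {
      p <- .stageParams(config, stage, list(curve = NULL, range = c(2, 100)))
      vd <- if (!is.null(p$curve)) readExceedance(p$curve) else state$voids
      if (is.null(vd)) .dependencyError(stage, "an exceedance curve (voids)")
      fit <- fitPowerLaw(vd, fitRange = as.numeric(p$range))
      path <- file.path(out, "fit.json")
      writePowerLawFit(fit, path, nVoids = length(voidSizes(vd)))
      list(fit = path, exponent = fit@exponent, r_squared = fit@rSquared)
    },
    compare = {
      p <- .stageParams(config, stage, list(
        observed = NULL, ensemble_dir = NULL, min_coverage = 0.5))
      obs <- if (!is.null(p$observed)) readExceedance(p$observed)
      else state$voids
      if (is.null(obs)) .dependencyError(stage, "an observed curve (voids)")
      if (is.null(p$ensemble_dir))
        .dependencyError(stage, "an ensemble directory of curve TSVs")
      files <- list.files(p$ensemble_dir, pattern = "\\.tsv$",
                          full.names = TRUE)
      if (!length(files))
        .dependencyError(stage, "ensemble curves in ensemble_dir")
      cmp <- compareToModel(obs, lapply(files, readExceedance),
                            minCoverage = p$min_coverage)
      path <- file.path(out, "compare.json")
      jsonlite::write_json(
        list(r_squared = cmp$rSquared, n_ensemble = cmp$nEnsemble,
             excluded_sizes = cmp$excludedSizes),
        path, auto_unbox = TRUE, digits = NA)
      list(compare = path, r_squared = cmp$rSquared)
    },
    synth_clones = {
      p <- .stageParams(config, stage, list(
        example = FALSE, nClones = 4, nSamples = 6, minCfSeparation = 0.15,
        nMutationsPerClone = 100, depthMean = 100, depthDispersion = 0))
      spec <- if (isTRUE(p$example))
        exampleTreeSpec(nMutations = p$nMutationsPerClone,
                        depthMean = p$depthMean,
                        depthDispersion = p$depthDispersion)
      else generateTreeScenario(p$nClones, p$nSamples, p$minCfSeparation,
                                seed = seeds$synth_clones,
                                nMutationsPerClone = p$nMutationsPerClone,
                                depthMean = p$depthMean,
                                depthDispersion = p$depthDispersion)
      sim <- generateCloneCounts(spec, seed = seeds$synth_clones)
      state$counts <- sim$counts
      path <- file.path(out, "counts.tsv")
      writeVariantCounts(sim$counts, path)
      writeTruth(sim$truth, out)
      list(counts = path, truth_dir = out)
    },
    cluster = {
      p <- .stageParams(config, stage, list(
        counts = NULL, burnIn = 5000, nSamples = 5000, concentration = 1,
        thin = 1))
      counts <- if (!is.null(p$counts)) readVariantCounts(p$counts)
      else state$counts
      if (is.null(counts))
        .dependencyError(stage, "a counts table (synth_clones)")
      cc <- gibbsCluster(counts, burnIn = p$burnIn, nSamples = p$nSamples,
                         concentration = p$concentration, thin = p$thin,
                         seed = seeds$cluster)
      state$clustering <- cc
      writeClustering(cc, out)
      list(dir = out, n_clusters = nClusters(cc))
    },
    filter = {
      p <- .stageParams(config, stage, list(minClusterSize = 50))
      if (is.null(state$clustering))
        .dependencyError(stage, "a clustering (cluster)")
      state$clustering <- filterClusters(state$clustering, p$minClusterSize)
      writeClustering(state$clustering, out)
      list(n_clusters = nClusters(state$clustering))
    },
    tree = {
      p <- .stageParams(config, stage, list(
        theta = NULL, minMedianVaf = 0.1, epsilon = 0.05,
        presenceFloor = 0.01))
      tr <- if (!is.null(p$theta)) {
        theta <- readClusterMatrix(p$theta)
        buildTree(computeCF(theta), epsilon = p$epsilon,
                  presenceFloor = p$presenceFloor)
      } else {
        if (is.null(state$clustering))
          .dependencyError(stage, "a clustering (cluster)")
        cc <- prefilterClusters(state$clustering, p$minMedianVaf)
        buildTree(cc, epsilon = p$epsilon, presenceFloor = p$presenceFloor)
      }
      state$tree <- tr
      path <- file.path(out, "tree.nwk")
      writeCloneTree(tr, path)
      list(tree = path, edges = paste0(path, ".edges.tsv"),
           n_roots = length(treeRoots(tr)))
    },
    territory = {
      p <- .stageParams(config, stage, list(
        sites = NULL, presenceFloor = 0.01))
      if (is.null(state$tree)) .dependencyError(stage, "a clone tree (tree)")
      if (is.null(p$sites)) .dependencyError(stage, "a site map TSV (sites)")
      mp <- mapClonesToSites(state$tree, readSiteMap(p$sites),
                             presenceFloor = p$presenceFloor)
      path <- file.path(out, "territory.tsv")
      utils::write.table(mp$composition, path, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      list(territory = path,
           territories = lapply(mp$territories, as.list))
    },
    .configError("unknown stage: ", stage))
}
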