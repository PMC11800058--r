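# End-to-end pipeline driven by a YAML configuration. A thin command-line
# wrapper lives in inst/scripts/run_pipeline.R; the exported functions are
# the interface.

#' Validate a pipeline run configuration
#'
#' Schema-checks the configuration (types, ranges, cross-field constraints
#' such as trs_size <= genotypes / environments) before any computation, so
#' misconfigurations fail fast with the offending field named.
#'
#' @param config a list (typically from \code{yaml::read_yaml}).
#' @return the validated config, with defaults filled in.
#' @export
validateRunConfig <- function(config) {
  need <- function(x, field, default = NULL) {
    if (!is.null(x)) return(x)
    if (!is.null(default)) return(default)
    stopf("config field '%s' is required", field)
  }
  sim <- need(config$sim, "sim", list())
  nG <- as.integer(need(sim$n_genotypes, "sim.n_genotypes", 100L))
  nE <- as.integer(need(sim$n_environments, "sim.n_environments", 5L))
  nM <- as.integer(need(sim$n_markers, "sim.n_markers", 500L))
  if (nG %% nE != 0)
    stopf("sim.n_genotypes (%d) must be divisible by sim.n_environments (%d)",
      nG, nE)
  des <- config$design
  trs <- as.integer(need(des$trs_sizes, "design.trs_sizes",
    round(nG / nE * c(1, 0.8, 0.6))))
  if (any(trs > nG / nE))
    stopf("design.trs_sizes may not exceed genotypes per environment (%d)",
      nG %/% nE)
  if (any(trs < 1)) stopf("design.trs_sizes must be positive")
  model <- config$model
  models <- need(model$models, "model.models", c("M1", "M2", "M3"))
  if (!all(models %in% c("M1", "M2", "M3")))
    stopf("model.models must be a subset of M1/M2/M3")
  list(
    sim = list(n_genotypes = nG, n_environments = nE, n_markers = nM,
      maf_range = as.numeric(need(sim$maf_range, "", c(0.05, 0.5))),
      missing_rate = as.numeric(need(sim$missing_rate, "", 0.03)),
      n_replicates = as.integer(need(sim$n_replicates, "", 2L)),
      n_blocks_per_rep = as.integer(need(sim$n_blocks_per_rep, "", 5L))),
    qc = list(max_missing = as.numeric(need(config$qc$max_missing, "", 0.20)),
      min_maf = as.numeric(need(config$qc$min_maf, "", 0.05)),
      min_callrate = as.numeric(need(config$qc$min_callrate, "", 0.80)),
      max_het = as.numeric(need(config$qc$max_het, "", 0.95))),
    design = list(trs_sizes = trs),
    model = list(models = models,
      n_iter = as.integer(need(model$n_iter, "", 12000L)),
      burn_in = as.integer(need(model$burn_in, "", 2000L)),
      thin = as.integer(need(model$thin, "", 5L)),
      prior_df = as.numeric(need(model$prior_df, "", 5))),
    evaluate = list(
      n_replicates = as.integer(need(config$evaluate$n_replicates, "", 10L))),
    seed = as.integer(need(config$seed, "", 1L)))
}

#' Run the full sparse-testing pipeline
#'
#' simulate -> QC -> impute -> GRM -> stage-1 BLUPs -> design grid ->
#' model fits -> evaluation. Writes plain-text artifacts (CSV/JSON) and a
#' run manifest (config, seeds, package version) to \code{outDir}. All
#' randomness flows from the single master seed through per-stage
#' substreams, so a config + seed pair reproduces every output.
#'
#' @param config list or path to a YAML file.
#' @param outDir output directory (created if absent).
#' @param seed optional override of the config seed.
#' @param stages subset of c("simulate","qc","stage1","design","evaluate");
#'   default all.
#' @param verbose print stage progress.
#' @return invisible list with the in-memory artifacts.
#' @export
runPipeline <- function(config, outDir, seed = NULL,
                        stages = c("simulate", "qc", "stage1", "design",
                          "evaluate"), verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validateRunConfig(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  out <- list(config = cfg)

  say("simulate: %d genotypes x %d environments, %d markers",
    cfg$sim$n_genotypes, cfg$sim$n_environments, cfg$sim$n_markers)
  sc <- simConfig(nGenotypes = cfg$sim$n_genotypes,
    nEnvironments = cfg$sim$n_environments, nMarkers = cfg$sim$n_markers,
    mafRange = cfg$sim$maf_range, missingRate = cfg$sim$missing_rate,
    nReplicates = cfg$sim$n_replicates,
    nBlocksPerRep = cfg$sim$n_blocks_per_rep,
    seed = childSeed(cfg$seed, 11))
  markersRaw <- simulateMarkers(sc)
  sig <- NULL
  if ("simulate" %in% stages) {
    qcr <- qcFilter(markersRaw, cfg$qc$max_missing, cfg$qc$min_maf,
      cfg$qc$min_callrate, cfg$qc$max_het)
    utils::write.csv(qcr$report, file.path(outDir, "qc_report.csv"),
      row.names = FALSE)
    markers <- imputeMean(qcr$markers)
    sig <- simulateEffects(markers, sc, seed = childSeed(cfg$seed, 12))
    plots <- simulatePlots(sig, sc, seed = childSeed(cfg$seed, 13))
    utils::write.csv(plots, file.path(outDir, "plots.csv"),
      row.names = FALSE)
    utils::write.csv(sig$signals, file.path(outDir, "true_signals.csv"),
      row.names = FALSE)
    writeMarkerCSV(markersRaw, file.path(outDir, "markers_raw.csv"))
    out$markers <- markers; out$plots <- plots; out$signals <- sig
    say("qc: kept %d of %d markers", qcr$nKept, qcr$nKept + qcr$nRemoved)
    grm <- computeGRM(markers)
    writeGRMcsv(grm, file.path(outDir, "grm.csv"))
    out$grm <- grm
  } else stopf("pipeline stages must start from 'simulate'")

  if ("stage1" %in% stages) {
    say("stage1: REML per environment")
    s1 <- fitStage1All(out$plots)
    utils::write.csv(s1$blups, file.path(outDir, "env_blups.csv"),
      row.names = FALSE)
    utils::write.csv(s1$summary, file.path(outDir, "stage1_summary.csv"),
      row.names = FALSE)
    out$stage1 <- s1
  }

  grid <- enumerateTable1(cfg$design$trs_sizes)
  utils::write.csv(grid, file.path(outDir, "design_grid.csv"),
    row.names = FALSE)
  if ("design" %in% stages) {
    part <- partitionNOL(genotypeIDs(out$grm), cfg$sim$n_environments,
      seed = childSeed(cfg$seed, 14))
    ex <- buildDesign(part, grid$trs_size[1], grid$n_ol[1],
      seed = childSeed(cfg$seed, 15))
    writeDesignJSON(ex, file.path(outDir, "design_example.json"))
    out$designExample <- ex
  }

  if ("evaluate" %in% stages) {
    say("evaluate: %d designs x %s x %d replicates", nrow(grid),
      paste(cfg$model$models, collapse = "/"), cfg$evaluate$n_replicates)
    et <- runExperiment(out$stage1$blups, out$grm, grid,
      models = cfg$model$models, nReplicates = cfg$evaluate$n_replicates,
      seed = childSeed(cfg$seed, 16), nIter = cfg$model$n_iter,
      burnIn = cfg$model$burn_in, thin = cfg$model$thin,
      priorDf = cfg$model$prior_df)
    utils::write.csv(et, file.path(outDir, "eval_records.csv"),
      row.names = FALSE)
    utils::write.csv(aggregateEval(et),
      file.path(outDir, "eval_summary.csv"), row.names = FALSE)
    out$evalTable <- et
  }

  manifest <- list(package = "sparseMET",
    version = as.character(utils::packageVersion("sparseMET")),
    seed = cfg$seed, config = cfg, timestamp = format(Sys.time()),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
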