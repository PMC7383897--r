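# Orchestration: a single YAML-configurable run binding all stages, and a
# fixture writer producing the default presets, focusing model and example
# data on disk.

#' Default run configuration
#'
#' @return named list mirroring the YAML schema of [runPipeline()]:
#'   donor id, geometry/fluid, candidate flow rates, bin edges, filter
#'   passage, event count and seed.
#' @export
defaultRunConfig <- function() {
  list(donor = "I",
       n_events = 10000,
       seed = 1,
       geometry = list(width = 170, height = 30, loops = 6,
                       curvature_radius = NA, n_outlets = 4),
       fluid = list(density = 1000, viscosity = 0.001),
       candidate_flow_rates = c(0.2, 0.4, 0.6, 0.8, 1.0),
       focusing_model = NULL,   # path to YAML; NULL = built-in model
       filter = list(pore_size = 3,
                     passage = list(enucleated = 0.40, nucleated = 0.004,
                                    nucleus = 0.004, debris = 0.5)),
       batch = list(volume = 10, dead_volume = 1.5, minutes = 10,
                    sedimentation_loss = 0.05))
}

.configFromYaml <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- utils::modifyList(defaultRunConfig(), yaml::read_yaml(path))
  cfg
}

#' Run the full pipeline from a configuration
#'
#' Executes the design table, ROC-based flow-rate selection over the
#' candidate rates, and the two-stage process model, writing the operating
#' table, AUC table, per-pair ROC curves, and the performance report into
#' `outputDir`. Identical (config, seed) runs produce identical artifacts;
#' the config's md5 hash is logged in the report for provenance.
#'
#' @param config a list as from [defaultRunConfig()], or a path to a YAML
#'   file with the same keys.
#' @param outputDir directory for artifacts (created if needed).
#' @return invisibly, a list with the selection, the report and the paths
#'   written.
#' @export
runPipeline <- function(config = defaultRunConfig(),
                        outputDir = tempfile("spiralsort-run-")) {
  cfgHash <- NA_character_
  if (is.character(config)) {
    cfgHash <- unname(tools::md5sum(config))
    config <- .configFromYaml(config)
  }
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)

  geom <- ChannelGeometry(
    width = config$geometry$width, height = config$geometry$height,
    loops = config$geometry$loops,
    curvatureRadius = if (is.null(config$geometry$curvature_radius))
      NA_real_ else as.numeric(config$geometry$curvature_radius),
    nOutlets = config$geometry$n_outlets)
  fluid <- Fluid(config$fluid$density, config$fluid$viscosity)
  model <- if (is.null(config$focusing_model)) defaultFocusingModel()
           else {
    if (!file.exists(config$focusing_model))
      stop("focusing model file not found: ", config$focusing_model,
           call. = FALSE)
    readFocusingModel(config$focusing_model)
  }
  preset <- donorPreset(config$donor)
  filt <- FilterModel(poreSize = config$filter$pore_size,
                      passage = unlist(config$filter$passage))
  batch <- BatchSpec(batchVolume = config$batch$volume,
                     deadVolume = config$batch$dead_volume,
                     processingMinutes = config$batch$minutes,
                     sedimentationLoss = config$batch$sedimentation_loss)

  opTab <- operatingTable(config$candidate_flow_rates, geom, fluid)
  utils::write.csv(opTab, file.path(outputDir, "operating_table.csv"),
                   row.names = FALSE)

  sel <- selectFlowRate(model, config$candidate_flow_rates,
                        seed = deriveSeed(config$seed, 1L))
  utils::write.csv(sel$aucTable, file.path(outputDir, "auc_table.csv"),
                   row.names = FALSE)

  # ROC curves for the chosen rate, one CSV per available contaminant
  for (cls in c("nucleated", "nucleus")) {
    if (is.null(modelEntry(model, cls, sel$flowRate, required = FALSE)))
      next
    enu <- sampleLateralPositions(model, "enucleated", sel$flowRate, 10000,
                                  deriveSeed(config$seed, 5L))
    con <- sampleLateralPositions(model, cls, sel$flowRate, 10000,
                                  deriveSeed(config$seed, 6L))
    roc <- rocCurve(enu, con)
    utils::write.csv(
      data.frame(cutoff = roc$cutoffs, fpr = roc$fpr, tpr = roc$tpr),
      file.path(outputDir, sprintf("roc_enucleated_vs_%s.csv", cls)),
      row.names = FALSE)
  }

  bins <- OutletBins(seq(0, model@width,
                         length.out = geom@nOutlets + 1L))
  report <- fullProcess(preset, model, sel$flowRate, bins, filt,
                        n = config$n_events, seed = config$seed,
                        batch = batch)
  report$configHash <- cfgHash
  reportPath <- file.path(outputDir, "report.json")
  writeReport(report, reportPath)
  utils::write.csv(as.data.frame(report$efficiency),
                   file.path(outputDir, "separation_efficiency.csv"))
  utils::write.csv(as.data.frame(report$purity),
                   file.path(outputDir, "purity_percent.csv"))

  invisible(list(flowRate = sel$flowRate, aucTable = sel$aucTable,
                 operatingTable = opTab, report = report,
                 outputDir = outputDir,
                 paths = list.files(outputDir, full.names = TRUE)))
}

#' Write the default fixture set to a directory
#'
#' Donor presets I-III, the measured focusing model, a default gate and run
#' config, example event CSVs per donor, and a rendered cytospin field with
#' its ground-truth table.
#'
#' @param dir target directory (created if needed).
#' @param seed integer seed for the stochastic fixtures.
#' @param nEvents events per donor CSV.
#' @return invisibly, the written paths.
#' @export
makeFixtures <- function(dir, seed = 1, nEvents = 2000) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir))
    stop("cannot create fixture directory: ", dir, call. = FALSE)
  paths <- character(0)
  add <- function(p) paths <<- c(paths, p)

  presets <- donorPresets()
  add(writeDonorPresets(presets, file.path(dir, "donor_presets.yaml")))
  add(writeFocusingModel(defaultFocusingModel(),
                         file.path(dir, "focusing_model.yaml")))
  add(writeGateConfig(defaultGates(presets$I),
                      file.path(dir, "gates_donor_I.yaml")))
  yaml::write_yaml(defaultRunConfig(), file.path(dir, "run_config.yaml"))
  add(file.path(dir, "run_config.yaml"))

  for (id in names(presets)) {
    tab <- generateEvents(presets[[id]], nEvents,
                          deriveSeed(seed, match(id, names(presets))))
    add(writeEventTable(tab, file.path(dir,
                                       sprintf("events_donor_%s.csv", id))))
  }

  spec <- randomCytospinSpec(seed = deriveSeed(seed, 11L))
  field <- renderCytospin(spec, seed = deriveSeed(seed, 12L))
  add(writeImageFile(field$image, file.path(dir, "cytospin_synthetic.png")))
  utils::write.csv(field$truth,
                   file.path(dir, "cytospin_synthetic_truth.csv"),
                   row.names = FALSE)
  add(file.path(dir, "cytospin_synthetic_truth.csv"))
  invisible(paths)
}
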