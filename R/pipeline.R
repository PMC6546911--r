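## Pipeline binding: one validated config drives simulate -> qc -> infer
## -> analyze with a master seed, per-stage artifacts and a manifest.

.STAGES <- c("simulate", "qc", "infer", "analyze")

.CONFIG_DEFAULTS <- list(
  scenario = "loading_atp",
  nTraces = 100L,
  duration = 60,
  rates = NULL,            # named "FROM->TO" overrides
  fretMean = NULL,
  substeps = NULL,
  photophysics = list(),   # overrides to photophysicsModel()
  signalFloor = 50,
  hmmK = NULL,             # NULL: BIC selection over hmmKRange
  hmmKRange = 2:4,
  hmmRestarts = 5L,
  hmmTol = 1e-6,
  tdpWindow = 6,
  heatmapTBin = 0.2,
  heatmapEBin = 0.02,
  seed = 1L,
  outdir = "clampfret_run"
)

#' Build a validated run configuration
#'
#' Fields default to the study conditions; any subset can be overridden.
#' The master \code{seed} fully determines every stochastic stage. The
#' config round-trips losslessly through [writeRunConfig()] /
#' [readRunConfig()].
#'
#' @param ... overrides of the default fields (unknown keys are
#'   rejected): scenario, nTraces, duration, rates, fretMean, substeps,
#'   photophysics (list of [photophysicsModel()] arguments),
#'   signalFloor, hmmK, hmmKRange, hmmRestarts, hmmTol, tdpWindow,
#'   heatmapTBin, heatmapEBin, seed, outdir.
#' @return a named list of class \code{clampfret_config}.
#' @export
#' @examples
#' runConfig(scenario = "unloading_atp", nTraces = 50, seed = 7)
runConfig <- function(...) {
  over <- list(...)
  bad <- setdiff(names(over), names(.CONFIG_DEFAULTS))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- .CONFIG_DEFAULTS
  cfg[names(over)] <- over
  if (!cfg$scenario %in% .SCENARIOS)
    stop("config key 'scenario' invalid: ", cfg$scenario)
  for (key in c("nTraces", "duration", "seed"))
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1L ||
        !is.finite(cfg[[key]]) || cfg[[key]] <= 0)
      stop("config key '", key, "' must be a positive number")
  class(cfg) <- "clampfret_config"
  cfg
}

#' Serialize / restore a run configuration (YAML)
#'
#' @param config from [runConfig()].
#' @param file path.
#' @export
writeRunConfig <- function(config, file) {
  yaml::write_yaml(unclass(config), file, precision = 15)
  invisible(file)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(file) {
  raw <- yaml::read_yaml(file)
  raw$hmmKRange <- as.integer(unlist(raw$hmmKRange))
  do.call(runConfig, raw)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages of simulate -> qc -> infer -> analyze in
#' order. Stage lists must be prefix-closed: a stage may only run if its
#' predecessor ran in this call or its artifacts already exist in
#' \code{outdir}. Identical config + seed reproduces byte-identical
#' trace CSVs. A JSON manifest records inputs, outputs, seeds and
#' per-stage counts.
#'
#' @param config from [runConfig()].
#' @param stages character subset of
#'   c("simulate", "qc", "infer", "analyze").
#' @return invisibly, a list with the stage outputs (traces, fret,
#'   selection, model, decoded, heatmap, tdp, dwells) and
#'   \code{manifest}.
#' @export
runPipeline <- function(config, stages = .STAGES) {
  stopifnot(inherits(config, "clampfret_config"))
  stages <- match.arg(stages, .STAGES, several.ok = TRUE)
  stages <- .STAGES[.STAGES %in% stages]
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    traces = file.path(outdir, "traces.csv"),
    truth = file.path(outdir, "truth_sidecar.csv"),
    report = file.path(outdir, "selection_report.csv"),
    fret = file.path(outdir, "fret_traces.csv"),
    model = file.path(outdir, "hmm_model.json"),
    decoded = file.path(outdir, "decoded_paths.csv"),
    heatmap = file.path(outdir, "heatmap.csv"),
    tdp = file.path(outdir, "tdp.csv"),
    dwells = file.path(outdir, "dwell_table.csv"),
    manifest = file.path(outdir, "manifest.json"))
  mode <- if (startsWith(config$scenario, "loading")) "loading" else
    "unloading"
  phot <- do.call(photophysicsModel, config$photophysics)
  scheme <- makeScenario(config$scenario, rates = config$rates,
                         fretMean = config$fretMean,
                         substeps = config$substeps)
  counts <- list()
  state <- new.env(parent = emptyenv())

  needUpstream <- function(stage, pathKeys) {
    ok <- all(vapply(paths[pathKeys], file.exists, logical(1)))
    if (!ok)
      stop("missing upstream artifact for stage '", stage,
           "': run earlier stages first")
  }

  if ("simulate" %in% stages) {
    traces <- simulateTraces(scheme, config$nTraces, config$duration,
                             phot, seed = config$seed)
    writeTraces(traces, paths$traces)
    writeTruthSidecar(traces, paths$truth)
    state$traces <- traces
    counts$simulate <- length(traces)
  }
  if ("qc" %in% stages) {
    if (is.null(state$traces)) {
      needUpstream("qc", "traces")
      state$traces <- readTraces(paths$traces)
    }
    bgD <- phot@backgroundDonor; bgA <- phot@backgroundAcceptor
    calib <- 6 * phot@donorBrightness
    sel <- selectTraces(state$traces, mode, bgD, bgA,
                        calibration = calib,
                        singleDonorBrightness = phot@donorBrightness)
    write.csv(sel$report, paths$report, row.names = FALSE,
              quote = FALSE)
    fret <- lapply(sel$selected, qcTrace, mode = mode,
                   backgroundDonor = bgD, backgroundAcceptor = bgA,
                   signalFloor = config$signalFloor,
                   singleDonorBrightness = phot@donorBrightness)
    fret <- Filter(function(ft) !any(is.na(ft@validWindow)), fret)
    writeFretTraces(fret, paths$fret)
    state$fret <- fret
    counts$qc <- c(selected = length(sel$selected),
                   analyzable = length(fret))
  }
  if ("infer" %in% stages) {
    if (is.null(state$fret)) needUpstream("infer", "fret")
    if (is.null(state$fret)) stop("qc artifacts must be rebuilt in ",
                                  "this session before 'infer'")
    model <- if (!is.null(config$hmmK)) {
      fitHmm(state$fret, config$hmmK, tol = config$hmmTol,
             nRestarts = config$hmmRestarts,
             seed = childSeed(config$seed, "infer"))
    } else {
      sel <- selectModel(state$fret, config$hmmKRange,
                         tol = config$hmmTol,
                         nRestarts = config$hmmRestarts,
                         seed = childSeed(config$seed, "infer"))
      sel$models[[paste0("K", sel$K)]]
    }
    writeHmmModel(model, paths$model)
    decoded <- lapply(state$fret, function(ft) decodePath(model, ft))
    writeDecodedPaths(decoded, state$fret, paths$decoded)
    state$model <- model
    state$decoded <- decoded
    counts$infer <- c(K = model@K, frames = model@nObs)
  }
  if ("analyze" %in% stages) {
    if (is.null(state$decoded))
      stop("missing upstream artifact for stage 'analyze': ",
           "run 'infer' in this call")
    anchor <- if (mode == "loading") "association" else "dissociation"
    aligned <- synchronize(state$fret, anchor)
    hm <- buildHeatMap(aligned, tBin = config$heatmapTBin,
                       eBin = config$heatmapEBin)
    writeMatrixCsv(hm, paths$heatmap)
    td <- transitionDensity(state$decoded, state$fret, state$model,
                            windowSeconds = config$tdpWindow,
                            side = if (mode == "loading") "first" else
                              "last",
                            eBin = config$heatmapEBin)
    writeMatrixCsv(td, paths$tdp)
    dw <- do.call(rbind, lapply(seq_len(state$model@K), function(s)
      dwellTimes(state$decoded, state$fret, s,
                 policy = "keep_flagged")))
    write.csv(dw, paths$dwells, row.names = FALSE, quote = FALSE)
    state$heatmap <- hm; state$tdp <- td; state$dwells <- dw
    counts$analyze <- c(alignedTraces = aligned$nTraces,
                        transitions = td@nTransitions)
  }
  manifest <- list(package = "clampFRET",
                   version = as.character(
                     utils::packageVersion("clampFRET")),
                   config = unclass(config), stages = stages,
                   seed = config$seed, counts = counts,
                   artifacts = unlist(paths[vapply(
                     paths, file.exists, logical(1))]))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(list(traces = state$traces, fret = state$fret,
                 selection = counts$qc, model = state$model,
                 decoded = state$decoded, heatmap = state$heatmap,
                 tdp = state$tdp, dwells = state$dwells,
                 manifest = manifest, paths = paths))
}
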