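# End-to-end orchestration: synth/load -> spikes -> bursts -> netgraph ->
# calcium, with per-replicate metrics, mean +/- SEM group summaries and a
# deterministic JSON run report.

#' Mean and standard error of the mean per group
#'
#' Summarizes replicate-level metric values as mean +/- SEM
#' (\code{SEM = sd / sqrt(n)}; 0 by convention for a single replicate,
#' which is flagged by its \code{n}).
#'
#' @param values numeric vector of per-replicate values.
#' @param labels group label per value (recycled if length 1).
#' @return data.frame with columns \code{group}, \code{mean}, \code{sem},
#'   \code{n}.
#' @examples
#' summarizeGroups(c(1, 2, 3), "sham")  # mean 2, sem 0.577
#' @export
summarizeGroups <- function(values, labels = "all") {
  if (!length(values)) stop("at least one replicate value is required")
  labels <- rep_len(as.character(labels), length(values))
  out <- do.call(rbind, lapply(split(values, labels), function(v) {
    data.frame(mean = mean(v),
               sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                     else 0,
               n = length(v))
  }))
  data.frame(group = rownames(out), out, row.names = NULL)
}

# Deterministic child seeds for the per-stage random streams.
.childSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.geometryFromConfig <- function(cfg) {
  g <- cfg$geometry
  if (is.null(g)) return(ElectrodeGeometry())
  ElectrodeGeometry(g$nRows %||% 8L, g$nCols %||% 8L, g$pitch %||% 150,
                    g$electrodeSize %||% 50)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stageLog <- function(stage, detail) {
  message(sprintf("[neuroburst] %-8s %s", stage, detail))
}

# Analyse one raster: bursts + functional graph. Returns metrics and
# writes stage outputs under dir.
.analyseRaster <- function(raster, geom, cfg, dir) {
  bp <- cfg$bursts
  bparams <- BurstDetectionParams(bp$thresholdCoef %||% 0.1,
                                  bp$minElectrodes %||% 4,
                                  bp$binWidth %||% 50)
  tsr <- computeTSR(raster, bparams@binWidth)
  bursts <- detectBursts(tsr, raster, bparams)
  bm <- burstMetrics(bursts)
  .stageLog("bursts", sprintf("%d bursts (%.1f / 10 min)", bm$nBursts,
                              bm$burstsPer10min))
  np <- cfg$netgraph
  sparams <- SynchronyParams(np$velocity %||% 0.4, np$delta %||% 2,
                             np$quantile %||% 0.95)
  graph <- NULL
  if (sum(electrodeSpikeCounts(raster) > 0L) >= 2L) {
    sm <- synchronyMatrix(raster, geom, sparams)
    graph <- selectEdges(sm, sparams@quantile)
    .stageLog("netgraph", sprintf("%d edges, %d hubs", nEdges(graph),
                                  nrow(hubTable(graph))))
  }
  writeRasterCsv(raster, file.path(dir, "raster.csv"))
  writeBurstsCsv(bursts, file.path(dir, "bursts.csv"))
  if (nBursts(bursts) > 0L)
    writeMatrixCsv(activationPattern(bursts, geom),
                   file.path(dir, "activation_map.csv"))
  if (!is.null(graph)) {
    writeMatrixCsv(synchronyValues(sm), file.path(dir, "synchrony_matrix.csv"))
    writeEdgesCsv(graph, file.path(dir, "edges.csv"))
    writeHubsCsv(graph, file.path(dir, "hubs.csv"))
    writeGraphML(graph, file.path(dir, "graph.graphml"))
  }
  list(nBursts = bm$nBursts, burstsPer10min = bm$burstsPer10min,
       meanSpikesPerBurst = bm$meanSpikesPerBurst,
       nSpikes = nSpikes(raster),
       nEdges = if (is.null(graph)) NA_integer_ else nEdges(graph),
       nHubs = if (is.null(graph)) NA_integer_ else nrow(hubTable(graph)))
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the configured stages -- synthetic data generation (optional),
#' spike detection from raw voltage (optional), TSR/burst analysis,
#' delayed-synchrony graph inference, and calcium transient analysis (when
#' traces are configured) -- writing every stage output plus a JSON run
#' report and a file manifest under \code{outDir}. Re-running with the same
#' configuration and seed reproduces byte-identical outputs.
#'
#' The configuration is a nested list (or path to a YAML file with the same
#' structure):
#' \describe{
#'   \item{geometry}{\code{nRows}, \code{nCols}, \code{pitch},
#'     \code{electrodeSize}.}
#'   \item{raster}{\code{path} to a raster CSV, or}
#'   \item{synth$burstRaster}{arguments of
#'     \code{\link{generateBurstRaster}} (plus optional
#'     \code{replicates}).}
#'   \item{raw}{\code{path} (base path of a flat-binary recording) to run
#'     spike detection on; \code{spikes} holds
#'     \linkS4class{SpikeDetectionParams} fields.}
#'   \item{bursts, netgraph, calcium}{stage parameter fields (see the
#'     corresponding params classes).}
#'   \item{calcium$path / synth$caTraces}{trace CSV path, or arguments of
#'     \code{\link{generateCaTraces}}.}
#' }
#'
#' @param config nested list or path to a YAML file.
#' @param outDir output directory (created if missing).
#' @param seed integer master seed; per-replicate and calcium streams use
#'   seeds derived from it deterministically.
#' @return Invisibly, the run report (also written as
#'   \code{report.json}).
#' @export
runPipeline <- function(config, outDir, seed = 1) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  geom <- .geometryFromConfig(config)
  nrep <- config$synth$burstRaster$replicates %||% 1L
  seeds <- .childSeeds(seed, nrep + 1L)

  repMetrics <- list()
  for (r in seq_len(nrep)) {
    dir <- if (nrep > 1L) file.path(outDir, sprintf("rep-%02d", r))
           else outDir
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    raster <- NULL
    if (!is.null(config$raster$path)) {
      raster <- readRasterCsv(config$raster$path,
                              config$raster$nElectrodes %||% NULL,
                              config$raster$duration %||% NULL)
      .stageLog("load", sprintf("raster %s (%d spikes)",
                                config$raster$path, nSpikes(raster)))
    } else if (!is.null(config$synth$burstRaster)) {
      sa <- config$synth$burstRaster
      gen <- generateBurstRaster(
        geom, duration = sa$duration %||% 60,
        burstRate = sa$burstRate %||% 30,
        burstDuration = unlist(sa$burstDuration %||% c(100, 500)),
        nElectrodesPerBurst = sa$nElectrodesPerBurst %||% 8,
        backgroundRate = sa$backgroundRate %||% 0.5,
        velocity = sa$velocity %||% 0.4,
        originPolicy = sa$originPolicy %||% "random",
        jitterSd = sa$jitterSd %||% 0.5,
        intraBurstRate = sa$intraBurstRate %||% 100,
        seed = seeds[r])
      raster <- gen$raster
      jsonlite::write_json(
        list(bursts = gen$truth$bursts,
             activeCells = lapply(gen$truth$electrodes, identity)),
        file.path(dir, "ground_truth.json"), digits = NA)
      .stageLog("synth", sprintf("replicate %d: %d spikes, %d bursts", r,
                                 nSpikes(raster), nrow(gen$truth$bursts)))
    } else if (!is.null(config$raw$path)) {
      rec <- readRawRecording(config$raw$path)
      sp <- config$spikes
      params <- SpikeDetectionParams(sp$ns %||% 4, sp$bandLow %||% 300,
                                     sp$bandHigh %||% 8000,
                                     sp$minIsi %||% 1,
                                     minWidth = sp$minWidth %||% 0.1)
      raster <- detectSpikes(rec, params)
      .stageLog("spikes", sprintf("%d spikes detected", nSpikes(raster)))
    } else {
      stop("config must provide raster$path, synth$burstRaster or raw$path")
    }
    repMetrics[[r]] <- .analyseRaster(raster, geom, config, dir)
  }

  caReport <- NULL
  if (!is.null(config$calcium$path) || !is.null(config$synth$caTraces)) {
    if (!is.null(config$calcium$path)) {
      traces <- readCaTracesCsv(config$calcium$path)
    } else {
      ca <- config$synth$caTraces
      gen <- generateCaTraces(
        nCells = ca$nCells %||% 100,
        activeFraction = ca$activeFraction %||% 0.97,
        rate = ca$rate %||% 6.9,
        meanDuration = ca$meanDuration %||% 6.23,
        amplitude = ca$amplitude %||% 50,
        noiseSd = ca$noiseSd %||% 1,
        frameRate = ca$frameRate %||% 4,
        duration = ca$duration %||% 180,
        seed = seeds[nrep + 1L])
      traces <- gen$traces
      writeCaTracesCsv(traces, file.path(outDir, "ca_traces.csv"))
    }
    params <- CaDetectionParams(config$calcium$accuracyCoef %||% 2)
    events <- detectCaEvents(traces, params)
    metrics <- caMetrics(events, nCells(traces),
                         recordingDuration(traces))
    utils::write.csv(
      data.frame(cell = events$cell - 1L, begin_s = events$begin,
                 end_s = events$end, duration_s = events$duration),
      file.path(outDir, "ca_events.csv"), row.names = FALSE, quote = FALSE)
    caReport <- metrics
    .stageLog("calcium", sprintf("%.1f%% active, %.2f osc/min",
                                 metrics$pctActive,
                                 metrics$freq %||% NA))
  }

  mnames <- c("nBursts", "burstsPer10min", "meanSpikesPerBurst", "nSpikes",
              "nEdges", "nHubs")
  perRep <- as.data.frame(do.call(rbind, lapply(repMetrics, function(m)
    unlist(m[mnames]))))
  summaries <- lapply(mnames, function(nm) {
    v <- perRep[[nm]]
    v <- v[is.finite(v)]
    if (length(v)) summarizeGroups(v, "all")[, c("mean", "sem", "n")]
    else NULL
  })
  names(summaries) <- mnames

  report <- list(
    package = "neuroburst",
    version = as.character(utils::packageVersion("neuroburst")),
    seed = seed, childSeeds = seeds,
    config = config,
    replicates = perRep,
    summary = summaries[!vapply(summaries, is.null, logical(1))],
    calcium = caReport)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")

  files <- sort(setdiff(list.files(outDir, recursive = TRUE),
                        "manifest.json"))
  manifest <- data.frame(
    file = files,
    md5 = unname(vapply(file.path(outDir, files),
                        function(f) as.character(tools::md5sum(f)),
                        character(1))),
    row.names = NULL)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE, digits = NA)
  invisible(report)
}
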