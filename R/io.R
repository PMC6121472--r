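# Plain-format readers and writers: raster CSV, raw recording as flat
# binary + JSON sidecar, calcium trace CSV + JSON metadata, and the various
# result tables. Electrode and cell indices are 0-based on disk, 1-based in
# R objects.

#' Read and write spike rasters as CSV
#'
#' The interchange format has a header \code{electrode,time_s} with 0-based
#' electrode indices and times in seconds, sorted by time.
#'
#' @param raster a \linkS4class{SpikeRaster}.
#' @param path file path.
#' @param nElectrodes,duration raster dimensions on read; inferred from the
#'   data when NULL (max index + 1, max time).
#' @return \code{readRasterCsv} returns a \linkS4class{SpikeRaster};
#'   \code{writeRasterCsv} returns \code{path} invisibly.
#' @export
writeRasterCsv <- function(raster, path) {
  df <- data.frame(electrode = spikeElectrodes(raster) - 1L,
                   time_s = spikeTimes(raster))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeRasterCsv
#' @export
readRasterCsv <- function(path, nElectrodes = NULL, duration = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("electrode", "time_s") %in% names(df)))
    stop("raster CSV must have columns electrode,time_s")
  if (is.null(nElectrodes))
    nElectrodes <- if (nrow(df)) max(df$electrode) + 1L else 1L
  if (is.null(duration))
    duration <- if (nrow(df)) max(df$time_s) else 1
  SpikeRaster(df$electrode + 1L, df$time_s, nElectrodes = nElectrodes,
              duration = duration)
}

#' Read and write raw recordings (flat binary + JSON sidecar)
#'
#' Samples are stored channel-major as little-endian float32 in
#' \code{<path>.bin}; rate, geometry and dimensions go to \code{<path>.json}.
#'
#' @param recording a \linkS4class{RawRecording}.
#' @param path base path (without extension).
#' @return \code{readRawRecording} returns a \linkS4class{RawRecording};
#'   the writer returns \code{path} invisibly.
#' @export
writeRawRecording <- function(recording, path) {
  sig <- signalMatrix(recording)
  geom <- geometry(recording)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(sig)), con, size = 4L, endian = "little")
  meta <- list(rate = samplingRate(recording),
               n_channels = nrow(sig), n_samples = ncol(sig),
               geometry = list(n_rows = geom@nRows, n_cols = geom@nCols,
                               pitch_um = geom@pitch,
                               electrode_size_um = geom@electrodeSize),
               units = "uV", layout = "channel-major float32 LE")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeRawRecording
#' @export
readRawRecording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  n <- meta$n_channels * meta$n_samples
  v <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  sig <- matrix(v, nrow = meta$n_channels, byrow = TRUE)
  geom <- ElectrodeGeometry(meta$geometry$n_rows, meta$geometry$n_cols,
                            meta$geometry$pitch_um,
                            meta$geometry$electrode_size_um)
  RawRecording(sig, rate = meta$rate, geometry = geom)
}

#' Read and write calcium trace sets
#'
#' Traces go to CSV (one column per cell, one row per frame, header
#' \code{cell_0,cell_1,...}); the frame rate goes to a JSON sidecar
#' \code{<path>.json} next to the CSV.
#'
#' @param traces a \linkS4class{CaTraceSet}.
#' @param path CSV file path.
#' @return \code{readCaTracesCsv} returns a \linkS4class{CaTraceSet}.
#' @export
writeCaTracesCsv <- function(traces, path) {
  m <- traceMatrix(traces)
  colnames(m) <- paste0("cell_", seq_len(ncol(m)) - 1L)
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(frame_rate = frameRate(traces)),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeCaTracesCsv
#' @export
readCaTracesCsv <- function(path) {
  m <- as.matrix(utils::read.csv(path))
  metaPath <- paste0(path, ".json")
  fr <- if (file.exists(metaPath))
    jsonlite::read_json(metaPath, simplifyVector = TRUE)$frame_rate
  else 4
  CaTraceSet(unname(m), frameRate = fr)
}

#' Write burst, edge, hub and activation-map tables
#'
#' Small CSV writers for the stage outputs: bursts
#' (\code{start_s,end_s,duration_s,n_spikes}), graph edges
#' (\code{src,dst,weight}, 0-based), hubs
#' (\code{electrode,degree,hub_coefficient}, 0-based), the synchrony matrix
#' and the activation map (one row per grid row).
#'
#' @param bursts a \linkS4class{NetworkBurstSet}.
#' @param graph a \linkS4class{SynchronyGraph}.
#' @param m a numeric matrix.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeBurstsCsv <- function(bursts, path) {
  bt <- burstTable(bursts)
  df <- data.frame(start_s = bt$start, end_s = bt$end,
                   duration_s = bt$duration, n_spikes = bt$nSpikes)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBurstsCsv
#' @export
writeEdgesCsv <- function(graph, path) {
  e <- graphEdges(graph)
  df <- data.frame(src = e$src - 1L, dst = e$dst - 1L, weight = e$weight)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBurstsCsv
#' @export
writeHubsCsv <- function(graph, path) {
  h <- hubTable(graph)
  df <- data.frame(electrode = h$electrode - 1L, degree = h$degree,
                   hub_coefficient = h$hubCoefficient)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBurstsCsv
#' @export
writeMatrixCsv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a synchrony graph as GraphML
#'
#' @param graph a \linkS4class{SynchronyGraph}.
#' @param path file path.
#' @export
writeGraphML <- function(graph, path) {
  igraph::write_graph(asIgraph(graph), path, format = "graphml")
  invisible(path)
}
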