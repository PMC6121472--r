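# Accessor and show methods for the core containers.

#' @rdname ElectrodeGeometry-class
setMethod("nElectrodes", "ElectrodeGeometry", function(object) {
  object@nRows * object@nCols
})

#' @rdname electrodePositions
setMethod("electrodePositions", "ElectrodeGeometry", function(object) {
  e <- seq_len(nElectrodes(object)) - 1L
  cbind(row = e %/% object@nCols + 1L, col = e %% object@nCols + 1L)
})

#' @rdname electrodePositions
setMethod("electrodeDistances", "ElectrodeGeometry", function(object) {
  pos <- electrodePositions(object)
  object@pitch * as.matrix(stats::dist(pos))
})

setMethod("show", "ElectrodeGeometry", function(object) {
  cat(sprintf(
    "ElectrodeGeometry: %d x %d grid (%d electrodes), pitch %g um, size %g um\n",
    object@nRows, object@nCols, nElectrodes(object), object@pitch,
    object@electrodeSize))
})

#' @rdname RawRecording-class
setMethod("samplingRate", "RawRecording", function(object) object@rate)

#' @rdname RawRecording-class
setMethod("signalMatrix", "RawRecording", function(object) object@signal)

#' @rdname RawRecording-class
setMethod("geometry", "RawRecording", function(object) object@geometry)

#' @rdname RawRecording-class
setMethod("recordingDuration", "RawRecording", function(object) {
  ncol(object@signal) / object@rate
})

setMethod("show", "RawRecording", function(object) {
  cat(sprintf(
    "RawRecording: %d channels x %d samples (%.3f s at %g Hz)\n",
    nrow(object@signal), ncol(object@signal), recordingDuration(object),
    object@rate))
})

#' @rdname SpikeRaster-class
setMethod("nSpikes", "SpikeRaster", function(object) length(object@time))

#' @rdname SpikeRaster-class
setMethod("spikeTimes", "SpikeRaster", function(object) object@time)

#' @rdname SpikeRaster-class
setMethod("spikeElectrodes", "SpikeRaster", function(object) object@electrode)

#' @rdname SpikeRaster-class
setMethod("nElectrodes", "SpikeRaster", function(object) object@nElectrodes)

#' @rdname SpikeRaster-class
setMethod("recordingDuration", "SpikeRaster", function(object) object@duration)

#' @rdname electrodeSpikeCounts
setMethod("electrodeSpikeCounts", "SpikeRaster", function(object) {
  tabulate(object@electrode, nbins = object@nElectrodes)
})

setMethod("show", "SpikeRaster", function(object) {
  cat(sprintf(
    "SpikeRaster: %d spikes on %d/%d electrodes over %.3f s\n",
    nSpikes(object), sum(electrodeSpikeCounts(object) > 0L),
    object@nElectrodes, object@duration))
})

setMethod("show", "TSRSeries", function(object) {
  cat(sprintf(
    "TSRSeries: %d bins of %g ms, %d spikes total, max %d spikes/bin\n",
    length(object@counts), object@binWidth, sum(object@counts),
    if (length(object@counts)) max(object@counts) else 0L))
})

#' @rdname NetworkBurstSet-class
setMethod("burstTable", "NetworkBurstSet", function(object) object@bursts)

#' @rdname NetworkBurstSet-class
setMethod("nBursts", "NetworkBurstSet", function(object) nrow(object@bursts))

#' @rdname NetworkBurstSet-class
setMethod("burstLatencies", "NetworkBurstSet",
          function(object) object@latencies)

#' @rdname NetworkBurstSet-class
setMethod("recordingDuration", "NetworkBurstSet",
          function(object) object@duration)

setMethod("show", "NetworkBurstSet", function(object) {
  cat(sprintf(
    "NetworkBurstSet: %d bursts over %.1f s (TSR threshold %.3f spikes/bin)\n",
    nBursts(object), object@duration, object@threshold))
  if (nBursts(object)) {
    cat(sprintf("  mean duration %.1f ms, mean %.1f spikes/burst\n",
                1000 * mean(object@bursts$duration),
                mean(object@bursts$nSpikes)))
  }
})

#' @rdname SynchronyMatrix-class
setMethod("synchronyValues", "SynchronyMatrix", function(object) object@values)

#' @rdname SynchronyMatrix-class
setMethod("electrodeSpikeCounts", "SynchronyMatrix",
          function(object) object@nSpikes)

#' @rdname SynchronyMatrix-class
setMethod("nElectrodes", "SynchronyMatrix", function(object) nrow(object@values))

setMethod("show", "SynchronyMatrix", function(object) {
  cat(sprintf(
    "SynchronyMatrix: %d electrodes (%d with spikes), velocity %g m/s, delta %g ms\n",
    nrow(object@values), sum(object@defined), object@velocity, object@delta))
})

#' @rdname SynchronyGraph-class
setMethod("graphEdges", "SynchronyGraph", function(object) object@edges)

#' @rdname SynchronyGraph-class
setMethod("nEdges", "SynchronyGraph", function(object) nrow(object@edges))

#' @rdname SynchronyGraph-class
setMethod("hubTable", "SynchronyGraph", function(object) object@hubs)

#' @rdname SynchronyGraph-class
setMethod("electrodeDegrees", "SynchronyGraph",
          function(object) object@degrees)

#' @rdname SynchronyGraph-class
setMethod("nElectrodes", "SynchronyGraph",
          function(object) object@nElectrodes)

setMethod("show", "SynchronyGraph", function(object) {
  cat(sprintf(
    "SynchronyGraph: %d directed edges (threshold %.4g), %d hubs\n",
    nEdges(object), object@threshold, nrow(object@hubs)))
})

#' @rdname CaTraceSet-class
setMethod("traceMatrix", "CaTraceSet", function(object) object@traces)

#' @rdname CaTraceSet-class
setMethod("frameRate", "CaTraceSet", function(object) object@frameRate)

#' @rdname CaTraceSet-class
setMethod("nCells", "CaTraceSet", function(object) ncol(object@traces))

#' @rdname CaTraceSet-class
setMethod("recordingDuration", "CaTraceSet", function(object) {
  nrow(object@traces) / object@frameRate
})

setMethod("show", "CaTraceSet", function(object) {
  cat(sprintf(
    "CaTraceSet: %d cells x %d frames (%.1f s at %g Hz)\n",
    nCells(object), nrow(object@traces), recordingDuration(object),
    object@frameRate))
})
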