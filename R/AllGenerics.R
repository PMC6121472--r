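#' @rdname ElectrodeGeometry-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("nElectrodes", function(object) standardGeneric("nElectrodes"))

#' Electrode grid positions and pairwise distances
#'
#' \code{electrodePositions} returns the (row, column) grid position of each
#' electrode; \code{electrodeDistances} the full matrix of pairwise
#' Euclidean distances in micrometres,
#' \eqn{d = pitch \sqrt{(r_1-r_2)^2 + (c_1-c_2)^2}}.
#'
#' @param object an \linkS4class{ElectrodeGeometry}.
#' @return \code{electrodePositions}: integer matrix (nElectrodes x 2);
#'   \code{electrodeDistances}: numeric matrix (nElectrodes x nElectrodes),
#'   zero on the diagonal.
#' @examples
#' d <- electrodeDistances(ElectrodeGeometry())
#' d[1, 2]  # neighbouring electrodes: one pitch apart
#' @export
setGeneric("electrodePositions",
           function(object) standardGeneric("electrodePositions"))

#' @rdname electrodePositions
#' @export
setGeneric("electrodeDistances",
           function(object) standardGeneric("electrodeDistances"))

#' @rdname RawRecording-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname RawRecording-class
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))

#' @rdname RawRecording-class
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))

#' Duration of a recording-like object, in seconds
#' @param object a \linkS4class{RawRecording}, \linkS4class{SpikeRaster} or
#'   \linkS4class{CaTraceSet}.
#' @export
setGeneric("recordingDuration",
           function(object) standardGeneric("recordingDuration"))

#' @rdname SpikeRaster-class
#' @export
setGeneric("nSpikes", function(object) standardGeneric("nSpikes"))

#' @rdname SpikeRaster-class
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))

#' @rdname SpikeRaster-class
#' @export
setGeneric("spikeElectrodes",
           function(object) standardGeneric("spikeElectrodes"))

#' Per-electrode spike counts
#' @param object a \linkS4class{SpikeRaster} or
#'   \linkS4class{SynchronyMatrix}.
#' @export
setGeneric("electrodeSpikeCounts",
           function(object) standardGeneric("electrodeSpikeCounts"))

#' @rdname NetworkBurstSet-class
#' @export
setGeneric("burstTable", function(object) standardGeneric("burstTable"))

#' @rdname NetworkBurstSet-class
#' @export
setGeneric("nBursts", function(object) standardGeneric("nBursts"))

#' @rdname NetworkBurstSet-class
#' @export
setGeneric("burstLatencies",
           function(object) standardGeneric("burstLatencies"))

#' @rdname SynchronyMatrix-class
#' @export
setGeneric("synchronyValues",
           function(object) standardGeneric("synchronyValues"))

#' @rdname SynchronyGraph-class
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))

#' @rdname SynchronyGraph-class
#' @export
setGeneric("nEdges", function(object) standardGeneric("nEdges"))

#' @rdname SynchronyGraph-class
#' @export
setGeneric("hubTable", function(object) standardGeneric("hubTable"))

#' @rdname SynchronyGraph-class
#' @export
setGeneric("electrodeDegrees",
           function(object) standardGeneric("electrodeDegrees"))

#' @rdname CaTraceSet-class
#' @export
setGeneric("traceMatrix", function(object) standardGeneric("traceMatrix"))

#' @rdname CaTraceSet-class
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))

#' @rdname CaTraceSet-class
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' Detect calcium transients
#'
#' Applies the derivative-threshold transient detector to a single
#' fluorescence trace or to every cell of a \linkS4class{CaTraceSet}. The
#' trace is first smoothed by averaging neighbouring frames, then
#' differentiated; the threshold is \code{accuracyCoef} times the standard
#' deviation of the derivative. A pulse opens where the derivative exceeds
#' the positive threshold on two consecutive frames (noise debounce) and
#' closes at the last sub-negative-threshold derivative frame before the
#' next pulse; unterminated pulses close at the trace end. Events separated
#' by less than two frames are merged.
#'
#' @param object numeric trace or \code{CaTraceSet}.
#' @param params a \linkS4class{CaDetectionParams}.
#' @param ... further arguments (for the numeric method: \code{frameRate}).
#' @return data.frame with columns \code{begin}, \code{end},
#'   \code{duration} (s); the \code{CaTraceSet} method prepends a
#'   \code{cell} column.
#' @examples
#' tr <- c(rep(20, 10), 20 + 50 * c(1, 2, 3) / 3, rep(70, 6),
#'         20 + 50 * c(2, 1, 0) / 3, rep(20, 18))
#' detectCaEvents(tr, CaDetectionParams(), frameRate = 4)
#' @export
setGeneric("detectCaEvents",
  function(object, params = CaDetectionParams(), ...)
    standardGeneric("detectCaEvents"))
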