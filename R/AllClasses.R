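#' @import methods
NULL

#' Planar multielectrode array geometry
#'
#' Describes the regular grid of recording electrodes. The default matches a
#' standard 64-channel array: an 8 x 8 grid with 150 um centre-to-centre
#' spacing and 50 x 50 um electrodes. Electrodes are indexed row-major,
#' starting at 1: electrode \eqn{e} sits at row \code{(e-1) \%/\% nCols + 1},
#' column \code{(e-1) \%\% nCols + 1}.
#'
#' @slot nRows,nCols integer, grid dimensions.
#' @slot pitch numeric, centre-to-centre electrode spacing in micrometres.
#' @slot electrodeSize numeric, electrode side length in micrometres.
#'
#' @export
setClass("ElectrodeGeometry",
  representation(
    nRows = "integer", nCols = "integer",
    pitch = "numeric", electrodeSize = "numeric"
  )
)

setValidity("ElectrodeGeometry", function(object) {
  msg <- NULL
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "nRows and nCols must be >= 1")
  if (object@pitch <= 0) msg <- c(msg, "pitch must be > 0")
  if (object@electrodeSize <= 0) msg <- c(msg, "electrodeSize must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' @param nRows,nCols grid dimensions (default 8 x 8).
#' @param pitch electrode spacing, um (default 150).
#' @param electrodeSize electrode side, um (default 50).
#' @return An \code{ElectrodeGeometry} object.
#' @examples
#' geom <- ElectrodeGeometry()
#' nElectrodes(geom)
#' @rdname ElectrodeGeometry-class
#' @export
ElectrodeGeometry <- function(nRows = 8L, nCols = 8L, pitch = 150,
                              electrodeSize = 50) {
  new("ElectrodeGeometry",
    nRows = as.integer(nRows), nCols = as.integer(nCols),
    pitch = as.numeric(pitch), electrodeSize = as.numeric(electrodeSize)
  )
}

#' Raw multichannel extracellular recording
#'
#' Voltage samples for every electrode of an array, in microvolts, sampled
#' at a common rate (20 kHz per channel by default throughout the package).
#'
#' @slot signal numeric matrix, channels x samples, uV.
#' @slot rate numeric, sampling rate in samples/s.
#' @slot geometry the \linkS4class{ElectrodeGeometry} of the array.
#'
#' @export
setClass("RawRecording",
  representation(signal = "matrix", rate = "numeric",
                 geometry = "ElectrodeGeometry")
)

setValidity("RawRecording", function(object) {
  msg <- NULL
  if (object@rate <= 0) msg <- c(msg, "rate must be > 0")
  if (nrow(object@signal) != nElectrodes(object@geometry))
    msg <- c(msg, "signal must have one row per electrode of the geometry")
  if (is.null(msg)) TRUE else msg
})

#' @param signal channels x samples numeric matrix (uV).
#' @param rate sampling rate, samples/s.
#' @param geometry an \code{ElectrodeGeometry}.
#' @rdname RawRecording-class
#' @export
RawRecording <- function(signal, rate = 20000, geometry = ElectrodeGeometry()) {
  new("RawRecording", signal = signal, rate = as.numeric(rate),
      geometry = geometry)
}

#' Spike raster: timestamped per-electrode spike events
#'
#' Events are stored sorted by time (ties broken by electrode index).
#' Electrode indices are 1-based inside R; the CSV interchange format
#' (\code{\link{writeRasterCsv}}) uses 0-based indices.
#'
#' @slot electrode integer vector, 1-based electrode index per event.
#' @slot time numeric vector, event times in seconds.
#' @slot nElectrodes integer, number of electrodes in the array.
#' @slot duration numeric, recording duration in seconds.
#' @slot metadata list, free-form provenance (e.g. per-channel sigma and
#'   detection threshold filled in by \code{\link{detectSpikes}}).
#'
#' @export
setClass("SpikeRaster",
  representation(
    electrode = "integer", time = "numeric",
    nElectrodes = "integer", duration = "numeric", metadata = "list"
  )
)

setValidity("SpikeRaster", function(object) {
  msg <- NULL
  if (length(object@electrode) != length(object@time))
    msg <- c(msg, "electrode and time must have equal length")
  if (length(object@time) && is.unsorted(object@time))
    msg <- c(msg, "events must be sorted by time")
  if (length(object@electrode) &&
      (min(object@electrode) < 1L || max(object@electrode) > object@nElectrodes))
    msg <- c(msg, "electrode indices must lie in [1, nElectrodes]")
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (length(object@time) &&
      (min(object@time) < 0 || max(object@time) > object@duration))
    msg <- c(msg, "spike times must lie in [0, duration]")
  if (is.null(msg)) TRUE else msg
})

#' @param electrode integer vector of 1-based electrode indices.
#' @param time numeric vector of spike times (s).
#' @param nElectrodes number of electrodes.
#' @param duration recording duration (s).
#' @param metadata optional list of provenance values.
#' @return A \code{SpikeRaster}; events are sorted by time on construction.
#' @rdname SpikeRaster-class
#' @export
SpikeRaster <- function(electrode, time, nElectrodes, duration,
                        metadata = list()) {
  o <- order(time, electrode)
  new("SpikeRaster",
    electrode = as.integer(electrode)[o], time = as.numeric(time)[o],
    nElectrodes = as.integer(nElectrodes), duration = as.numeric(duration),
    metadata = metadata
  )
}

#' Total spiking rate series
#'
#' Spike counts summed over all electrodes in consecutive time bins
#' (50 ms by default), together with the per-bin number of distinct active
#' electrodes. This is the signal on which network bursts are detected.
#'
#' @slot counts integer vector of per-bin spike counts.
#' @slot activeElectrodes integer vector, per-bin count of distinct
#'   electrodes with at least one spike.
#' @slot binWidth numeric, bin width in milliseconds.
#' @slot duration numeric, raster duration in seconds.
#'
#' @export
setClass("TSRSeries",
  representation(
    counts = "integer", activeElectrodes = "integer",
    binWidth = "numeric", duration = "numeric"
  )
)

setValidity("TSRSeries", function(object) {
  msg <- NULL
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be > 0")
  if (length(object@counts) != length(object@activeElectrodes))
    msg <- c(msg, "counts and activeElectrodes must have equal length")
  if (length(object@counts) !=
      ceiling(object@duration * 1000 / object@binWidth))
    msg <- c(msg, "length(counts) must equal ceiling(duration/binWidth)")
  if (length(object@counts) && min(object@counts) < 0L)
    msg <- c(msg, "counts must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Segmented network bursts
#'
#' Result container of \code{\link{detectBursts}}: one row per burst with
#' boundaries refined to the first/last spike of the suprathreshold run,
#' plus per-electrode first-spike latencies for activation-pattern analysis.
#'
#' @slot bursts data.frame with columns \code{start}, \code{end},
#'   \code{duration} (s) and \code{nSpikes}.
#' @slot latencies list (one element per burst) of named numeric vectors:
#'   first-spike latency in ms from burst start, names are electrode indices;
#'   electrodes silent in the burst are absent.
#' @slot duration numeric, duration of the analysed recording (s).
#' @slot threshold numeric, the TSR threshold used (spikes/bin).
#' @slot binWidth numeric, TSR bin width (ms).
#'
#' @export
setClass("NetworkBurstSet",
  representation(
    bursts = "data.frame", latencies = "list", duration = "numeric",
    threshold = "numeric", binWidth = "numeric"
  )
)

setValidity("NetworkBurstSet", function(object) {
  msg <- NULL
  if (nrow(object@bursts) != length(object@latencies))
    msg <- c(msg, "one latency vector is required per burst")
  if (nrow(object@bursts) && any(object@bursts$end <= object@bursts$start))
    msg <- c(msg, "burst end must exceed burst start")
  if (is.null(msg)) TRUE else msg
})

#' Delayed-synchrony cross-correlation matrix
#'
#' \code{C[i, j]} is the fraction of spikes on postsynaptic electrode j that
#' have at least one spike on presynaptic electrode i within the tolerance
#' window centred on the distance-proportional axonal delay. Entries
#' involving an electrode without spikes carry no synchrony evidence and are
#' flagged undefined (stored as 0).
#'
#' @slot values numeric matrix, nElectrodes x nElectrodes, entries in
#'   [0, 1],
#'   zero diagonal.
#' @slot nSpikes integer vector, per-electrode spike counts (n_j).
#' @slot defined logical vector, TRUE for electrodes with >= 1 spike.
#' @slot velocity numeric, assumed conduction velocity, m/s.
#' @slot delta numeric, tolerance window width, ms.
#'
#' @export
setClass("SynchronyMatrix",
  representation(
    values = "matrix", nSpikes = "integer", defined = "logical",
    velocity = "numeric", delta = "numeric"
  )
)

setValidity("SynchronyMatrix", function(object) {
  msg <- NULL
  n <- nrow(object@values)
  if (ncol(object@values) != n) msg <- c(msg, "C must be square")
  if (length(object@nSpikes) != n || length(object@defined) != n)
    msg <- c(msg, "nSpikes and defined must have one entry per electrode")
  if (n && (min(object@values) < 0 || max(object@values) > 1))
    msg <- c(msg, "entries of C must lie in [0, 1]")
  if (n && any(diag(object@values) != 0))
    msg <- c(msg, "diagonal of C must be zero")
  if (is.null(msg)) TRUE else msg
})

#' Functional graph of delayed-synchrony connections
#'
#' Directed edges selected from the top tail of the synchrony matrix, with
#' per-electrode degrees and the identified hubs. The hub coefficient of an
#' electrode is its incident-edge count divided by the total number of edges
#' in the graph, so coefficients over all electrodes sum to 2.
#'
#' @slot edges data.frame with columns \code{src}, \code{dst},
#'   \code{weight}.
#' @slot degrees integer vector, incident-edge count per electrode.
#' @slot hubs data.frame with columns \code{electrode}, \code{degree},
#'   \code{hubCoefficient}.
#' @slot threshold numeric, the synchrony value above which edges were kept.
#' @slot nElectrodes integer.
#'
#' @export
setClass("SynchronyGraph",
  representation(
    edges = "data.frame", degrees = "integer", hubs = "data.frame",
    threshold = "numeric", nElectrodes = "integer"
  )
)

setValidity("SynchronyGraph", function(object) {
  msg <- NULL
  if (length(object@degrees) != object@nElectrodes)
    msg <- c(msg, "degrees must have one entry per electrode")
  if (nrow(object@edges) &&
      sum(object@degrees) != 2L * nrow(object@edges))
    msg <- c(msg, "degrees must sum to twice the number of edges")
  if (is.null(msg)) TRUE else msg
})

#' Calcium fluorescence trace set
#'
#' Per-cell somatic fluorescence traces in relative units 0-255, sampled at
#' a common frame rate (4 Hz by default).
#'
#' @slot traces numeric matrix, frames x cells.
#' @slot frameRate numeric, frames/s.
#'
#' @export
setClass("CaTraceSet",
  representation(traces = "matrix", frameRate = "numeric")
)

setValidity("CaTraceSet", function(object) {
  msg <- NULL
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (length(object@traces) &&
      (min(object@traces) < 0 || max(object@traces) > 255))
    msg <- c(msg, "fluorescence values must lie in [0, 255]")
  if (is.null(msg)) TRUE else msg
})

#' @param traces frames x cells numeric matrix (relative units 0-255).
#' @param frameRate frames per second (default 4).
#' @rdname CaTraceSet-class
#' @export
CaTraceSet <- function(traces, frameRate = 4) {
  new("CaTraceSet", traces = as.matrix(traces),
      frameRate = as.numeric(frameRate))
}

#' Planted directed connectivity for the synthetic generator
#'
#' A set of directed presynaptic -> postsynaptic electrode pairs with a
#' per-edge spike transmission probability and a common conduction velocity.
#' Used by \code{\link{generateConnectedRaster}} to plant ground-truth
#' delayed-synchronous structure.
#'
#' @slot edges data.frame with integer columns \code{src}, \code{dst}
#'   (1-based electrode indices, no self-edges).
#' @slot transmissionProb numeric in [0, 1], recycled over edges.
#' @slot velocity numeric, conduction velocity in m/s.
#'
#' @export
setClass("PlantedConnectivity",
  representation(edges = "data.frame", transmissionProb = "numeric",
                 velocity = "numeric")
)

setValidity("PlantedConnectivity", function(object) {
  msg <- NULL
  if (!all(c("src", "dst") %in% names(object@edges)))
    msg <- c(msg, "edges must have columns src and dst")
  else if (nrow(object@edges) && any(object@edges$src == object@edges$dst))
    msg <- c(msg, "self-edges are not allowed")
  if (any(object@transmissionProb < 0 | object@transmissionProb > 1))
    msg <- c(msg, "transmissionProb must lie in [0, 1]")
  if (object@velocity <= 0) msg <- c(msg, "velocity must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' @param edges data.frame with columns \code{src}, \code{dst}.
#' @param transmissionProb per-edge transmission probability (recycled).
#' @param velocity conduction velocity, m/s.
#' @rdname PlantedConnectivity-class
#' @export
PlantedConnectivity <- function(edges, transmissionProb = 1, velocity = 0.4) {
  edges <- as.data.frame(edges)
  edges$src <- as.integer(edges$src)
  edges$dst <- as.integer(edges$dst)
  new("PlantedConnectivity", edges = edges,
      transmissionProb = rep_len(as.numeric(transmissionProb), nrow(edges)),
      velocity = as.numeric(velocity))
}
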