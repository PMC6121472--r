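# Network burst analysis: total spiking rate, TSR-threshold burst
# segmentation, summary metrics and burst activation patterns.

#' Compute the total spiking rate (TSR)
#'
#' Counts spikes from all electrodes in consecutive half-open time bins
#' \code{[k*bw, (k+1)*bw)} of width \code{binWidth} ms (default 50), along
#' with the number of distinct active electrodes per bin.
#'
#' @param raster a \linkS4class{SpikeRaster}.
#' @param binWidth bin width, ms.
#' @return A \linkS4class{TSRSeries}; \code{sum(counts)} equals the total
#'   number of raster spikes.
#' @export
computeTSR <- function(raster, binWidth = 50) {
  if (binWidth <= 0) stop("binWidth must be > 0")
  dur <- recordingDuration(raster)
  nBins <- as.integer(ceiling(dur * 1000 / binWidth))
  bin <- pmin(nBins, floor(spikeTimes(raster) * 1000 / binWidth) + 1L)
  counts <- tabulate(bin, nbins = nBins)
  act <- integer(nBins)
  if (nSpikes(raster)) {
    u <- unique(data.frame(bin = bin, el = spikeElectrodes(raster)))
    act <- tabulate(u$bin, nbins = nBins)
  }
  new("TSRSeries", counts = as.integer(counts),
      activeElectrodes = as.integer(act), binWidth = binWidth,
      duration = dur)
}

#' Detect small network bursts from the TSR
#'
#' The burst threshold is \code{thresholdCoef} times the standard deviation
#' of the TSR series (0.1 x sigma_TSR by default). A burst is a maximal run
#' of consecutive bins with counts above threshold that contains at least
#' one bin with \code{minElectrodes} or more distinct active electrodes.
#' Burst boundaries are refined from the bin edges to the first and last
#' spike inside the run, so that estimated durations are not limited to the
#' 50-ms bin resolution.
#'
#' @param tsr a \linkS4class{TSRSeries} computed from \code{raster} with
#'   the same bin width.
#' @param raster the \linkS4class{SpikeRaster} the TSR was computed from.
#' @param params a \linkS4class{BurstDetectionParams}.
#' @return A \linkS4class{NetworkBurstSet} (empty if the TSR is flat).
#' @export
detectBursts <- function(tsr, raster, params = BurstDetectionParams()) {
  stopifnot(is(tsr, "TSRSeries"), is(raster, "SpikeRaster"))
  if (abs(tsr@binWidth - params@binWidth) > 1e-9)
    warning("TSR bin width differs from params binWidth; using the TSR's")
  bw <- tsr@binWidth / 1000  # s
  counts <- tsr@counts
  emptySet <- new("NetworkBurstSet",
    bursts = data.frame(start = numeric(0), end = numeric(0),
                        duration = numeric(0), nSpikes = integer(0)),
    latencies = list(), duration = tsr@duration, threshold = NA_real_,
    binWidth = tsr@binWidth)
  if (!length(counts) || all(counts == 0L)) return(emptySet)

  threshold <- params@thresholdCoef * stats::sd(counts)
  above <- counts > threshold
  if (!any(above)) { emptySet@threshold <- threshold; return(emptySet) }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]; ends <- ends[r$values]

  tm <- spikeTimes(raster); el <- spikeElectrodes(raster)
  rows <- list(); lats <- list()
  for (k in seq_along(starts)) {
    if (max(tsr@activeElectrodes[starts[k]:ends[k]]) < params@minElectrodes)
      next
    w0 <- (starts[k] - 1L) * bw
    w1 <- ends[k] * bw
    inWin <- which(tm >= w0 & tm < w1)
    if (length(inWin) < 2L) next
    t0 <- tm[inWin[1]]
    t1 <- tm[inWin[length(inWin)]]
    if (t1 <= t0) next
    lat <- tapply((tm[inWin] - t0) * 1000, el[inWin], min)
    rows[[length(rows) + 1L]] <- data.frame(
      start = t0, end = t1, duration = t1 - t0, nSpikes = length(inWin))
    lats[[length(lats) + 1L]] <-
      stats::setNames(as.numeric(lat), names(lat))
  }
  if (!length(rows)) { emptySet@threshold <- threshold; return(emptySet) }
  new("NetworkBurstSet", bursts = do.call(rbind, rows), latencies = lats,
      duration = tsr@duration, threshold = threshold,
      binWidth = tsr@binWidth)
}

#' Summary metrics of network burst activity
#'
#' @param bursts a \linkS4class{NetworkBurstSet}.
#' @param duration recording duration, s; defaults to the one stored in
#'   \code{bursts}.
#' @return list with \code{nBursts}, \code{burstsPer10min}
#'   (\code{nBursts * 600 / duration}) and \code{meanSpikesPerBurst}
#'   (NA when no bursts were detected).
#' @examples
#' # 93 bursts in 300 s correspond to 186 bursts / 10 min
#' @export
burstMetrics <- function(bursts, duration = recordingDuration(bursts)) {
  stopifnot(duration > 0)
  n <- nBursts(bursts)
  list(nBursts = n,
       burstsPer10min = n * 600 / duration,
       meanSpikesPerBurst = if (n) mean(burstTable(bursts)$nSpikes)
                            else NA_real_)
}

#' Burst activation pattern
#'
#' For every electrode, the median over bursts of its first-spike latency
#' within the burst -- the map of how activity propagates across the array
#' during a network burst. Electrodes that never fire within a burst are NA.
#'
#' @param bursts a \linkS4class{NetworkBurstSet} with at least one burst.
#' @param geometry the \linkS4class{ElectrodeGeometry} used to arrange the
#'   map.
#' @return numeric matrix (nRows x nCols) of median first-spike latencies
#'   in ms, arranged by grid position.
#' @export
activationPattern <- function(bursts, geometry = ElectrodeGeometry()) {
  if (!nBursts(bursts)) stop("activation pattern requires >= 1 burst")
  nEl <- nElectrodes(geometry)
  lat <- vector("list", nEl)
  for (b in burstLatencies(bursts)) {
    idx <- as.integer(names(b))
    for (k in seq_along(idx))
      lat[[idx[k]]] <- c(lat[[idx[k]]], b[[k]])
  }
  med <- vapply(lat, function(v) if (length(v)) stats::median(v)
                                 else NA_real_, numeric(1))
  matrix(med, nrow = geometry@nRows, ncol = geometry@nCols, byrow = TRUE)
}
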