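# Shared fixtures and independent oracles used across the suite.

# Brute-force delayed-synchrony matrix: direct all-pairs window scan,
# deliberately independent of the findInterval-based implementation.
bruteSynchrony <- function(raster, geom, velocity = 0.4, delta = 2) {
  n <- nElectrodes(raster)
  dmat <- electrodeDistances(geom)
  el <- spikeElectrodes(raster)
  tm <- spikeTimes(raster)
  half <- delta / 2000
  C <- matrix(0, n, n)
  for (j in seq_len(n)) {
    tj <- tm[el == j]
    if (!length(tj)) next
    for (i in seq_len(n)) {
      if (i == j) next
      ti <- tm[el == i]
      if (!length(ti)) next
      tau <- dmat[i, j] * 1e-6 / velocity
      cnt <- 0L
      for (t in tj)
        if (any(ti >= t - tau - half & ti <= t - tau + half))
          cnt <- cnt + 1L
      C[i, j] <- cnt / length(tj)
    }
  }
  C
}

# Match detected bursts to planted ones by interval overlap and return the
# per-planted-burst relative duration errors (NA when undetected).
burstDurationErrors <- function(truth, detected) {
  bt <- burstTable(detected)
  vapply(seq_len(nrow(truth)), function(k) {
    ov <- pmin(bt$end, truth$end[k]) - pmax(bt$start, truth$start[k])
    if (!nrow(bt) || max(ov) <= 0) return(NA_real_)
    m <- which.max(ov)
    abs(bt$duration[m] - truth$duration[k]) / truth$duration[k]
  }, numeric(1))
}

# A raster with a dense multi-electrode volley on known electrodes/times and
# nothing else; handy for exact boundary checks.
volleyRaster <- function(electrodes, times, nElectrodes = 64,
                         duration = 10) {
  SpikeRaster(electrodes, times, nElectrodes = nElectrodes,
              duration = duration)
}
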