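# Synthetic-data generators: raw voltage traces, burst rasters with planted
# ground truth, rasters with planted directed connectivity, and calcium
# traces with planted events. These are first-class, tested generators: every
# downstream stage of the pipeline is validated by recovering the structure
# planted here.

# Biphasic extracellular spike template: negative trough then smaller
# positive overshoot, 1 ms total width, peak |amplitude| = 1 at the trough.
.spikeTemplate <- function(rate) {
  n <- max(3L, round(rate / 1000))  # 1 ms of samples
  tt <- seq(0, 1, length.out = n + 1L)
  w <- ifelse(tt <= 0.5, -sin(pi * tt / 0.5),
              0.4 * sin(pi * (tt - 0.5) / 0.5))
  list(w = w, trough = which.min(w))
}

#' Generate a raw multichannel recording with scheduled spikes
#'
#' Each channel is white Gaussian background noise of the requested standard
#' deviation; at every scheduled time a biphasic spike waveform (1 ms wide,
#' negative trough followed by a 40\% positive overshoot) is added with its
#' trough at the scheduled sample and peak absolute amplitude as requested.
#'
#' @param geometry an \linkS4class{ElectrodeGeometry}.
#' @param duration recording length, s.
#' @param noiseSd noise standard deviation, uV.
#' @param spikeSchedule data.frame with columns \code{electrode} (1-based),
#'   \code{time} (s) and \code{amplitude} (uV, peak absolute value, > 0), or
#'   NULL for noise only.
#' @param rate sampling rate, samples/s (default 20000).
#' @param seed integer seed; identical seed and parameters give
#'   bit-identical output.
#' @return A \linkS4class{RawRecording}.
#' @examples
#' geom <- ElectrodeGeometry(2, 2)
#' rec <- generateRawRecording(geom, duration = 0.1, noiseSd = 5, seed = 1)
#' @export
generateRawRecording <- function(geometry, duration, noiseSd,
                                 spikeSchedule = NULL, rate = 20000,
                                 seed = NULL) {
  stopifnot(duration > 0, noiseSd >= 0, rate > 0)
  if (!is.null(seed)) set.seed(seed)
  nCh <- nElectrodes(geometry)
  nS <- round(rate * duration)
  sig <- if (noiseSd > 0) {
    matrix(stats::rnorm(nCh * nS, sd = noiseSd), nrow = nCh)
  } else {
    matrix(0, nrow = nCh, ncol = nS)
  }
  if (!is.null(spikeSchedule) && nrow(spikeSchedule)) {
    if (any(spikeSchedule$time < 0 | spikeSchedule$time >= duration))
      stop("scheduled spike times must lie in [0, duration)")
    if (any(spikeSchedule$amplitude <= 0))
      stop("spike amplitudes must be positive (peak absolute value)")
    if (any(spikeSchedule$electrode < 1 | spikeSchedule$electrode > nCh))
      stop("scheduled electrode index out of range")
    tpl <- .spikeTemplate(rate)
    for (k in seq_len(nrow(spikeSchedule))) {
      ch <- spikeSchedule$electrode[k]
      at <- round(spikeSchedule$time[k] * rate) + 1L
      idx <- at - tpl$trough + seq_along(tpl$w)
      keep <- idx >= 1L & idx <= nS
      sig[ch, idx[keep]] <- sig[ch, idx[keep]] +
        spikeSchedule$amplitude[k] * tpl$w[keep]
    }
  }
  RawRecording(sig, rate = rate, geometry = geometry)
}

# Renewal burst-start times: a dead time covering the burst plus a minimum
# silent gap of two TSR bins (100 ms) -- cultures bursting at several Hz do
# so quasi-periodically -- plus exponential waiting that absorbs the
# remaining mean interval, so the mean inter-burst interval is 60/burstRate.
.drawBurstSchedule <- function(duration, burstRate, durRange,
                               minGap = 0.1) {
  mu <- 60 / burstRate
  if (mu < mean(durRange) + minGap)
    stop("burst rate too high for the requested burst durations")
  slack <- max(0.001, mu - mean(durRange) - minGap)
  starts <- numeric(0)
  durs <- numeric(0)
  t <- stats::rexp(1, rate = 1 / mu)
  repeat {
    d <- stats::runif(1, durRange[1], durRange[2])
    if (t + d >= duration) break
    starts <- c(starts, t)
    durs <- c(durs, d)
    t <- t + d + minGap + stats::rexp(1, rate = 1 / slack)
  }
  list(start = starts, duration = durs)
}

#' Generate a spike raster with planted network bursts
#'
#' Burst start times follow a stationary renewal process (exponential
#' waiting plus a dead time covering the burst, so bursts never overlap).
#' Within each burst an origin electrode fires first and every other
#' participating electrode follows after a distance-proportional propagation
#' delay (distance / velocity) plus non-negative Gaussian jitter; each
#' participant then fires a Poisson train until the burst end. Background
#' activity is homogeneous Poisson on every electrode. The returned ground
#' truth lists every planted burst with its true boundaries, participants
#' and per-electrode first-spike latencies.
#'
#' @param geometry an \linkS4class{ElectrodeGeometry}.
#' @param duration raster length, s.
#' @param burstRate planted burst rate, bursts/min.
#' @param burstDuration burst length in ms: a single value or a
#'   \code{c(min, max)} range sampled uniformly per burst.
#' @param nElectrodesPerBurst number of participating electrodes (origin
#'   plus its nearest neighbours; default 8).
#' @param backgroundRate background rate, spikes/s/electrode (default 0.5).
#' @param velocity propagation velocity, m/s (default 0.4).
#' @param originPolicy \code{"random"} (origin drawn per burst) or
#'   \code{"corner"} (electrode 1 originates every burst).
#' @param jitterSd propagation jitter SD, ms, truncated at zero
#'   (default 0.5).
#' @param intraBurstRate within-burst firing rate per participating
#'   electrode, spikes/s (default 100).
#' @param seed integer seed.
#' @return list with elements \code{raster} (a \linkS4class{SpikeRaster})
#'   and \code{truth}: a list with \code{bursts} (data.frame \code{start},
#'   \code{end}, \code{duration} in s, \code{origin}), \code{electrodes}
#'   (list of participating index vectors) and \code{firstSpike} (list of
#'   named vectors, planted first-spike latency in ms from burst start).
#' @export
generateBurstRaster <- function(geometry, duration, burstRate,
                                burstDuration = c(100, 1000),
                                nElectrodesPerBurst = 8,
                                backgroundRate = 0.5, velocity = 0.4,
                                originPolicy = c("random", "corner"),
                                jitterSd = 0.5, intraBurstRate = 100,
                                seed = NULL) {
  originPolicy <- match.arg(originPolicy)
  if (any(burstDuration <= 0)) stop("burstDuration must be positive")
  stopifnot(burstRate >= 0, backgroundRate >= 0,
            nElectrodesPerBurst >= 1,
            nElectrodesPerBurst <= nElectrodes(geometry))
  if (!is.null(seed)) set.seed(seed)
  nEl <- nElectrodes(geometry)
  durRange <- range(burstDuration) / 1000  # s
  dmat <- electrodeDistances(geometry)

  el <- integer(0); tm <- numeric(0)
  truthBursts <- data.frame(start = numeric(0), end = numeric(0),
                            duration = numeric(0), origin = integer(0))
  truthEl <- list(); truthLat <- list()

  if (burstRate > 0) {
    sched <- .drawBurstSchedule(duration, burstRate, durRange)
    for (b in seq_along(sched$start)) {
      t0 <- sched$start[b]
      dur <- sched$duration[b]
      origin <- if (originPolicy == "corner") 1L else sample.int(nEl, 1)
      part <- order(dmat[origin, ], seq_len(nEl))[seq_len(nElectrodesPerBurst)]
      lat <- dmat[origin, part] / (velocity * 1000)  # um / (um/ms) -> ms
      if (jitterSd > 0)
        lat <- lat + pmax(0, stats::rnorm(length(part), 0, jitterSd))
      lat <- pmin(lat, dur * 1000)  # never beyond the burst itself
      for (k in seq_along(part)) {
        tFirst <- t0 + lat[k] / 1000
        nMore <- stats::rpois(1, intraBurstRate * max(0, t0 + dur - tFirst))
        tt <- c(tFirst,
                if (nMore) sort(stats::runif(nMore, tFirst, t0 + dur)))
        el <- c(el, rep(part[k], length(tt)))
        tm <- c(tm, tt)
      }
      truthBursts <- rbind(truthBursts, data.frame(
        start = t0, end = t0 + dur, duration = dur, origin = origin))
      truthEl[[b]] <- part
      truthLat[[b]] <- stats::setNames(lat, part)
    }
  }

  if (backgroundRate > 0) {
    for (e in seq_len(nEl)) {
      n <- stats::rpois(1, backgroundRate * duration)
      if (n) {
        el <- c(el, rep(e, n))
        tm <- c(tm, stats::runif(n, 0, duration))
      }
    }
  }

  raster <- SpikeRaster(el, tm, nElectrodes = nEl, duration = duration)
  list(raster = raster,
       truth = list(bursts = truthBursts, electrodes = truthEl,
                    firstSpike = truthLat))
}

#' Generate a spike raster with planted directed connectivity
#'
#' Presynaptic electrodes fire independent homogeneous Poisson trains; each
#' source spike on edge (i, j) is copied to electrode j with the edge's
#' transmission probability, delayed by distance(i, j) / velocity (plus
#' optional Gaussian jitter). The copies are delayed-synchronous pairs by
#' construction, the planted counterpart of the functional connections the
#' synchrony matrix is designed to recover. Only intrinsic source spikes are
#' transmitted (no multi-hop relaying).
#'
#' @param connectivity a \linkS4class{PlantedConnectivity}.
#' @param geometry an \linkS4class{ElectrodeGeometry}.
#' @param duration raster length, s.
#' @param sourceRate intrinsic firing rate of presynaptic electrodes,
#'   spikes/s.
#' @param backgroundRate independent Poisson background on every electrode,
#'   spikes/s (default 0).
#' @param jitterSd transmission jitter SD in ms (default 0: copies arrive at
#'   exactly the distance-proportional delay).
#' @param seed integer seed.
#' @return A \linkS4class{SpikeRaster}.
#' @export
generateConnectedRaster <- function(connectivity, geometry, duration,
                                    sourceRate, backgroundRate = 0,
                                    jitterSd = 0, seed = NULL) {
  stopifnot(is(connectivity, "PlantedConnectivity"), sourceRate > 0,
            duration > 0, backgroundRate >= 0)
  if (!is.null(seed)) set.seed(seed)
  nEl <- nElectrodes(geometry)
  dmat <- electrodeDistances(geometry)
  edges <- connectivity@edges
  if (nrow(edges) &&
      (max(edges$src, edges$dst) > nEl || min(edges$src, edges$dst) < 1L))
    stop("connectivity edge indices exceed the geometry")

  sources <- sort(unique(edges$src))
  srcTrain <- list()
  for (s in sources) {
    n <- stats::rpois(1, sourceRate * duration)
    srcTrain[[as.character(s)]] <- sort(stats::runif(n, 0, duration))
  }

  el <- integer(0); tm <- numeric(0)
  for (s in sources) {
    tt <- srcTrain[[as.character(s)]]
    el <- c(el, rep(s, length(tt)))
    tm <- c(tm, tt)
  }
  for (k in seq_len(nrow(edges))) {
    src <- edges$src[k]; dst <- edges$dst[k]
    p <- connectivity@transmissionProb[k]
    tt <- srcTrain[[as.character(src)]]
    keep <- if (p >= 1) rep(TRUE, length(tt)) else
      stats::runif(length(tt)) < p
    tt <- tt[keep] + dmat[src, dst] * 1e-6 / connectivity@velocity
    if (jitterSd > 0)
      tt <- tt + stats::rnorm(length(tt), 0, jitterSd / 1000)
    tt <- tt[tt >= 0 & tt < duration]
    el <- c(el, rep(dst, length(tt)))
    tm <- c(tm, tt)
  }
  if (backgroundRate > 0) {
    for (e in seq_len(nEl)) {
      n <- stats::rpois(1, backgroundRate * duration)
      if (n) {
        el <- c(el, rep(e, n))
        tm <- c(tm, stats::runif(n, 0, duration))
      }
    }
  }
  SpikeRaster(el, tm, nElectrodes = nEl, duration = duration)
}

#' Planted hub connectivity on the central block of the array
#'
#' Convenience constructor of a \linkS4class{PlantedConnectivity} with
#' \code{nHubs} source electrodes in the central 2 x 2 block of the grid,
#' each projecting to four targets three grid steps away along the array
#' axes. The targets of one hub are equidistant from it and pairwise more
#' than 400 um apart, so that two targets of the same hub never mimic a
#' delayed-synchronous pair at the default tolerance (velocity 0.4 m/s,
#' delta 2 ms). Requires at least a 7 x 7 grid.
#'
#' @param geometry an \linkS4class{ElectrodeGeometry} (>= 7 rows and cols).
#' @param nHubs number of hub sources, 1..4.
#' @param transmissionProb per-edge transmission probability (default 0.9).
#' @param velocity conduction velocity, m/s.
#' @return A \linkS4class{PlantedConnectivity}.
#' @export
plantedHubConnectivity <- function(geometry, nHubs = 4,
                                   transmissionProb = 0.9, velocity = 0.4) {
  stopifnot(geometry@nRows >= 7L, geometry@nCols >= 7L,
            nHubs >= 1, nHubs <= 4)
  cr <- geometry@nRows %/% 2L
  cc <- geometry@nCols %/% 2L
  hubPos <- list(c(cr, cc), c(cr, cc + 1L), c(cr + 1L, cc),
                 c(cr + 1L, cc + 1L))[seq_len(nHubs)]
  off <- list(c(-3L, 0L), c(3L, 0L), c(0L, -3L), c(0L, 3L))
  toIdx <- function(rc) (rc[1] - 1L) * geometry@nCols + rc[2]
  src <- integer(0); dst <- integer(0)
  for (h in hubPos) {
    for (o in off) {
      tg <- h + o
      if (tg[1] >= 1L && tg[1] <= geometry@nRows &&
          tg[2] >= 1L && tg[2] <= geometry@nCols) {
        src <- c(src, toIdx(h)); dst <- c(dst, toIdx(tg))
      }
    }
  }
  PlantedConnectivity(data.frame(src = src, dst = dst),
                      transmissionProb = transmissionProb,
                      velocity = velocity)
}

# One calcium event pulse sampled at the trace frame times. rel is time
# within the event as a fraction of its duration. Linear rise over
# max(3 frames, 12% of duration), plateau, exponential terminal decay with
# tau = 0.5 s over the final 2*tau of the event.
.caPulse <- function(tRel, d, frameRate) {
  rspan <- max(0.12, 3 / (d * frameRate))
  tau <- 0.5
  fspan <- min(0.6, 2 * tau / d)
  ifelse(tRel < 0 | tRel > 1, 0,
    ifelse(tRel < rspan, tRel / rspan,
      ifelse(tRel < 1 - fspan, 1,
        exp(-(tRel - (1 - fspan)) * d / tau))))
}

#' Generate calcium fluorescence traces with planted events
#'
#' A configurable fraction of cells is active; each active cell carries
#' calcium events drawn from a renewal process with the requested rate and
#' (Gaussian-distributed) duration. Events do not overlap: the generator
#' enforces a 1.5 s minimum inter-event gap, the refractory interval between
#' network-wide calcium oscillations. The pulse shape is a linear rise
#' (about 0.75 s), a plateau, and an exponential terminal decay (tau 0.5 s)
#' ending at the event boundary. Remaining cells are baseline plus noise.
#' Trace values are clipped to [0, 255].
#'
#' @param nCells number of cells.
#' @param activeFraction fraction of cells carrying events, in [0, 1];
#'   \code{round(nCells * activeFraction)} cells are active.
#' @param rate event rate per active cell, events/min.
#' @param meanDuration mean event duration, s.
#' @param amplitude event amplitude, relative units.
#' @param noiseSd additive Gaussian noise SD, relative units.
#' @param frameRate sampling rate, Hz (default 4).
#' @param duration trace length, s.
#' @param baseline resting fluorescence, relative units (default 20).
#' @param seed integer seed.
#' @return list with \code{traces} (a \linkS4class{CaTraceSet}) and
#'   \code{truth}: list with \code{events} (data.frame \code{cell},
#'   \code{begin}, \code{end}), \code{activeCells} (integer vector),
#'   \code{rate} and \code{meanDuration} (the requested presets).
#' @export
generateCaTraces <- function(nCells, activeFraction, rate, meanDuration,
                             amplitude = 50, noiseSd = 1, frameRate = 4,
                             duration = 180, baseline = 20, seed = NULL) {
  stopifnot(nCells >= 1, activeFraction >= 0, activeFraction <= 1,
            rate >= 0, meanDuration > 0, frameRate > 0, duration > 0)
  if (!is.null(seed)) set.seed(seed)
  if (baseline + amplitude > 250)
    warning("amplitude + baseline close to 255: events will clip")
  nFrames <- round(duration * frameRate)
  nActive <- round(nCells * activeFraction)
  activeCells <- sort(sample.int(nCells, nActive))
  tt <- (seq_len(nFrames) - 0.5) / frameRate
  traces <- matrix(baseline, nrow = nFrames, ncol = nCells)
  ev <- data.frame(cell = integer(0), begin = numeric(0), end = numeric(0))
  minGap <- 1.5
  for (c in activeCells) {
    if (rate <= 0) next
    t <- stats::rexp(1, rate / 60)
    repeat {
      d <- max(1.5, stats::rnorm(1, meanDuration, 0.15 * meanDuration))
      if (t + d >= duration) break
      traces[, c] <- traces[, c] + amplitude * .caPulse((tt - t) / d, d,
                                                        frameRate)
      ev <- rbind(ev, data.frame(cell = c, begin = t, end = t + d))
      gapMean <- max(0.2, 60 / rate - meanDuration - minGap)
      t <- t + d + minGap + stats::rexp(1, 1 / gapMean)
    }
  }
  if (noiseSd > 0)
    traces <- traces + stats::rnorm(length(traces), 0, noiseSd)
  traces <- pmax(pmin(traces, 255), 0)  # keeps the frames x cells dim
  list(traces = CaTraceSet(traces, frameRate = frameRate),
       truth = list(events = ev, activeCells = activeCells, rate = rate,
                    meanDuration = meanDuration))
}
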