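# Spike detection: zero-phase band-pass filtering, median-based noise
# estimation and amplitude-threshold crossing detection.

#' Zero-phase band-pass filter a recording
#'
#' Filters every channel with a Butterworth band-pass (order 2, applied
#' forward and backward with \code{signal::filtfilt}, i.e. zero-phase and
#' 4th order effective). Output length equals input length.
#'
#' @param recording a \linkS4class{RawRecording}.
#' @param bandLow,bandHigh corner frequencies, Hz (defaults 300 and 8000,
#'   the 0.3-8 kHz band).
#' @return A filtered \linkS4class{RawRecording}.
#' @export
bandpassFilter <- function(recording, bandLow = 300, bandHigh = 8000) {
  rate <- samplingRate(recording)
  if (bandHigh >= rate / 2)
    stop("bandHigh must be below the Nyquist frequency (rate/2)")
  if (bandLow <= 0 || bandLow >= bandHigh)
    stop("band corners must satisfy 0 < bandLow < bandHigh")
  bf <- signal::butter(2, c(bandLow, bandHigh) / (rate / 2), type = "pass")
  sig <- signalMatrix(recording)
  out <- t(apply(sig, 1, function(ch) signal::filtfilt(bf, ch)))
  RawRecording(out, rate = rate, geometry = geometry(recording))
}

#' Median-based noise estimate and detection threshold
#'
#' \eqn{\sigma = median(|x|) / 0.6745}: the median absolute signal rescaled
#' to the standard deviation of a spike-free Gaussian background (0.6745 is
#' the 0.75 quantile of the standard normal). Unlike a direct SD, the median
#' is barely inflated by the spikes themselves, so the resulting threshold
#' \eqn{T = N_S \sigma} depends only weakly on firing rate.
#'
#' @param channel numeric vector of (band-passed) samples, uV.
#' @param normConst normalization constant (default 0.6745).
#' @param ns detection coefficient used for the threshold (default 4).
#' @return list with \code{sigma} and \code{threshold} (\code{ns * sigma}),
#'   both in uV.
#' @examples
#' estimateSigma(rnorm(1e4, sd = 5))
#' @export
estimateSigma <- function(channel, normConst = 0.6745, ns = 4) {
  if (!length(channel)) stop("channel must be non-empty")
  sigma <- stats::median(abs(channel)) / normConst
  list(sigma = sigma, threshold = ns * sigma)
}

# Threshold-crossing detection on one channel. Returns sample indices of
# the extremum of each accepted suprathreshold run.
.detectChannel <- function(x, threshold, minIsiSamples, minWidthSamples) {
  above <- abs(x) > threshold
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minWidthSamples
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(integer(0))
  peaks <- mapply(function(s, e) s - 1L + which.max(abs(x[s:e])),
                  starts, ends)
  # minimal interspike interval: keep the first spike, drop later crossings
  # within minIsi of the last accepted one
  acc <- peaks[1]
  last <- peaks[1]
  for (p in peaks[-1]) {
    if (p - last >= minIsiSamples) {
      acc <- c(acc, p)
      last <- p
    }
  }
  acc
}

#' Detect extracellular spikes by median-normalized thresholding
#'
#' Per channel, the detection threshold is \eqn{T = N_S \sigma} with
#' \eqn{\sigma} from \code{\link{estimateSigma}}. Maximal runs of samples
#' with \eqn{|x| > T} (both polarities) lasting at least
#' \code{params@minWidth} ms are spikes, timed at the extremum of the run;
#' subsequent crossings within the minimal interspike interval of an
#' accepted spike are discarded.
#'
#' @param recording a \linkS4class{RawRecording}; band-passed internally
#'   unless \code{filter = FALSE}.
#' @param params a \linkS4class{SpikeDetectionParams}.
#' @param filter logical: apply \code{\link{bandpassFilter}} first
#'   (default TRUE). Pass FALSE for recordings that are already filtered or
#'   noise-free synthetic input.
#' @return A \linkS4class{SpikeRaster}; per-channel \code{sigma} and
#'   \code{threshold} (uV) are stored in its \code{metadata}.
#' @export
detectSpikes <- function(recording, params = SpikeDetectionParams(),
                         filter = TRUE) {
  rate <- samplingRate(recording)
  if (filter)
    recording <- bandpassFilter(recording, params@bandLow, params@bandHigh)
  sig <- signalMatrix(recording)
  nCh <- nrow(sig)

  minIsiSamples <- round(params@minIsi / 1000 * rate)
  if (minIsiSamples < 2L) {
    warning("minIsi shorter than 2 samples; clamped")
    minIsiSamples <- 2L
  }
  minWidthSamples <- max(1L, round(params@minWidth / 1000 * rate))

  sigmas <- numeric(nCh); thresholds <- numeric(nCh)
  el <- integer(0); tm <- numeric(0)
  for (ch in seq_len(nCh)) {
    est <- estimateSigma(sig[ch, ], params@normConst, params@ns)
    sigmas[ch] <- est$sigma
    thresholds[ch] <- est$threshold
    if (est$threshold <= 0) next  # silent channel: no spikes
    idx <- .detectChannel(sig[ch, ], est$threshold, minIsiSamples,
                          minWidthSamples)
    if (length(idx)) {
      el <- c(el, rep(ch, length(idx)))
      tm <- c(tm, (idx - 1L) / rate)
    }
  }
  SpikeRaster(el, tm, nElectrodes = nCh,
              duration = recordingDuration(recording),
              metadata = list(sigma = sigmas, threshold = thresholds,
                              ns = params@ns))
}
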