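#' Spike detection parameters
#'
#' Parameters of the median-normalized amplitude-threshold spike detector.
#' The detection threshold on each channel is \eqn{T = N_S \sigma} with
#' \eqn{\sigma = median(|x|) / 0.6745}, the median absolute signal rescaled
#' to the standard deviation of a spike-free Gaussian background.
#'
#' @slot ns detection coefficient \eqn{N_S} (default 4).
#' @slot bandLow,bandHigh band-pass corner frequencies, Hz (defaults 300 and
#'   8000).
#' @slot minIsi minimal interspike interval, ms (default 1).
#' @slot normConst median-to-SD normalization constant (0.6745, the 0.75
#'   quantile of the standard normal).
#' @slot minWidth minimal time the rectified signal must stay above
#'   threshold for a crossing to count as a spike, ms (default 0.1, i.e.
#'   2 samples at 20 kHz). Single-sample threshold excursions of filtered
#'   Gaussian noise are rejected by this rule; see the package vignette.
#'
#' @export
setClass("SpikeDetectionParams",
  representation(
    ns = "numeric", bandLow = "numeric", bandHigh = "numeric",
    minIsi = "numeric", normConst = "numeric", minWidth = "numeric"
  )
)

setValidity("SpikeDetectionParams", function(object) {
  msg <- NULL
  if (object@ns <= 0) msg <- c(msg, "ns must be > 0")
  if (object@bandLow <= 0 || object@bandHigh <= object@bandLow)
    msg <- c(msg, "band corners must satisfy 0 < bandLow < bandHigh")
  if (object@minIsi <= 0) msg <- c(msg, "minIsi must be > 0")
  if (object@normConst <= 0) msg <- c(msg, "normConst must be > 0")
  if (object@minWidth < 0) msg <- c(msg, "minWidth must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' @param ns,bandLow,bandHigh,minIsi,normConst,minWidth see slot
#'   documentation.
#' @rdname SpikeDetectionParams-class
#' @export
SpikeDetectionParams <- function(ns = 4, bandLow = 300, bandHigh = 8000,
                                 minIsi = 1, normConst = 0.6745,
                                 minWidth = 0.1) {
  new("SpikeDetectionParams", ns = ns, bandLow = bandLow,
      bandHigh = bandHigh, minIsi = minIsi, normConst = normConst,
      minWidth = minWidth)
}

#' Network burst detection parameters
#'
#' @slot thresholdCoef burst threshold as a fraction of the standard
#'   deviation of the total spiking rate (default 0.1).
#' @slot minElectrodes minimal number of distinct electrodes that must be
#'   active within one bin of the burst (default 4).
#' @slot binWidth TSR bin width, ms (default 50).
#'
#' @export
setClass("BurstDetectionParams",
  representation(thresholdCoef = "numeric", minElectrodes = "integer",
                 binWidth = "numeric")
)

setValidity("BurstDetectionParams", function(object) {
  msg <- NULL
  if (object@thresholdCoef <= 0) msg <- c(msg, "thresholdCoef must be > 0")
  if (object@minElectrodes < 1L)
    msg <- c(msg, "minElectrodes must be >= 1")
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' @param thresholdCoef,minElectrodes,binWidth see slot documentation.
#' @rdname BurstDetectionParams-class
#' @export
BurstDetectionParams <- function(thresholdCoef = 0.1, minElectrodes = 4,
                                 binWidth = 50) {
  new("BurstDetectionParams", thresholdCoef = thresholdCoef,
      minElectrodes = as.integer(minElectrodes), binWidth = binWidth)
}

#' Delayed-synchrony parameters
#'
#' @slot velocity assumed axonal conduction velocity, m/s (default 0.4,
#'   unmyelinated cortical axon scale); sets the proportionality between
#'   inter-electrode distance and expected spike delay.
#' @slot delta tolerance window width around the expected delay, ms
#'   (default 2).
#' @slot quantile fraction of the synchrony distribution below the edge
#'   selection threshold (default 0.95: the largest 5\% of coefficients
#'   become edges).
#'
#' @export
setClass("SynchronyParams",
  representation(velocity = "numeric", delta = "numeric",
                 quantile = "numeric")
)

setValidity("SynchronyParams", function(object) {
  msg <- NULL
  if (object@velocity <= 0) msg <- c(msg, "velocity must be > 0")
  if (object@delta <= 0) msg <- c(msg, "delta must be > 0")
  if (object@quantile <= 0 || object@quantile >= 1)
    msg <- c(msg, "quantile must lie in (0, 1)")
  if (is.null(msg)) TRUE else msg
})

#' @param velocity,delta,quantile see slot documentation.
#' @rdname SynchronyParams-class
#' @export
SynchronyParams <- function(velocity = 0.4, delta = 2, quantile = 0.95) {
  new("SynchronyParams", velocity = velocity, delta = delta,
      quantile = quantile)
}

#' Calcium transient detection parameters
#'
#' @slot accuracyCoef detection accuracy coefficient: the derivative
#'   threshold is this coefficient times the standard deviation of the
#'   derivative of the (smoothed) trace. Default 2.
#'
#' @export
setClass("CaDetectionParams", representation(accuracyCoef = "numeric"))

setValidity("CaDetectionParams", function(object) {
  if (object@accuracyCoef <= 0) "accuracyCoef must be > 0" else TRUE
})

#' @param accuracyCoef see slot documentation.
#' @rdname CaDetectionParams-class
#' @export
CaDetectionParams <- function(accuracyCoef = 2) {
  new("CaDetectionParams", accuracyCoef = accuracyCoef)
}
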