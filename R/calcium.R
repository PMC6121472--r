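# Calcium transient detection from fluorescence traces and population
# metrics (fraction of active cells, oscillation frequency, duration).

#' Smooth a fluorescence trace by neighbour averaging
#'
#' \code{output[k] = (input[k] + input[k+1]) / 2}; the output is one frame
#' shorter than the input.
#'
#' @param trace numeric vector, length >= 2.
#' @return numeric vector of length \code{length(trace) - 1}.
#' @examples
#' smoothTrace(c(0, 2, 4))  # 1 3
#' @export
smoothTrace <- function(trace) {
  if (length(trace) < 2L) stop("trace must have length >= 2")
  (trace[-length(trace)] + trace[-1L]) / 2
}

#' First difference of a trace
#'
#' \code{d[k] = trace[k+1] - trace[k]}.
#'
#' @param trace numeric vector, length >= 2.
#' @return numeric vector of length \code{length(trace) - 1}.
#' @examples
#' derivativeTrace(c(1, 4, 2))  # 3 -2
#' @export
derivativeTrace <- function(trace) {
  if (length(trace) < 2L) stop("trace must have length >= 2")
  diff(trace)
}

# Core detector on one trace. Returns a matrix of (begin, end) derivative
# frame indices, or NULL.
.detectCaPulses <- function(trace, accuracyCoef) {
  d <- derivativeTrace(smoothTrace(trace))
  threshold <- accuracyCoef * stats::sd(d)
  if (!is.finite(threshold) || threshold == 0) return(NULL)
  up <- d > threshold
  dn <- d < -threshold
  # a pulse opens on two consecutive suprathreshold derivative frames
  # (debounce against single-frame noise excursions)
  cand <- which(up[-length(up)] & up[-1L])
  if (!length(cand)) return(NULL)
  beg <- cand[c(TRUE, diff(cand) > 1L)]
  dnIdx <- which(dn)
  out <- matrix(0L, nrow = length(beg), ncol = 2L)
  for (i in seq_along(beg)) {
    b <- beg[i]
    nxt <- if (i < length(beg)) beg[i + 1L] else length(d) + 1L
    fall <- dnIdx[dnIdx > b & dnIdx < nxt]
    e <- if (length(fall)) max(fall) + 1L else nxt - 1L
    out[i, ] <- c(b, e)
  }
  # merge events separated by fewer than 2 frames
  if (nrow(out) > 1L) {
    merged <- out[1L, , drop = FALSE]
    for (k in 2:nrow(out)) {
      if (out[k, 1L] - merged[nrow(merged), 2L] < 2L)
        merged[nrow(merged), 2L] <- out[k, 2L]
      else
        merged <- rbind(merged, out[k, , drop = FALSE])
    }
    out <- merged
  }
  out
}

#' @rdname detectCaEvents
#' @param frameRate frames per second (numeric method only; default 4).
setMethod("detectCaEvents", "numeric",
  function(object, params = CaDetectionParams(), frameRate = 4) {
    if (length(object) < 3L) stop("trace must have length >= 3")
    pulses <- .detectCaPulses(object, params@accuracyCoef)
    if (is.null(pulses) || !nrow(pulses))
      return(data.frame(begin = numeric(0), end = numeric(0),
                        duration = numeric(0)))
    begin <- pulses[, 1L] / frameRate
    end <- pulses[, 2L] / frameRate
    data.frame(begin = begin, end = end, duration = end - begin)
  })

#' @rdname detectCaEvents
setMethod("detectCaEvents", "CaTraceSet",
  function(object, params = CaDetectionParams()) {
    tr <- traceMatrix(object)
    out <- lapply(seq_len(ncol(tr)), function(c) {
      ev <- detectCaEvents(tr[, c], params, frameRate = frameRate(object))
      if (nrow(ev)) cbind(cell = c, ev) else NULL
    })
    out <- do.call(rbind, out)
    if (is.null(out))
      out <- data.frame(cell = integer(0), begin = numeric(0),
                        end = numeric(0), duration = numeric(0))
    rownames(out) <- NULL
    out
  })

#' Population metrics of calcium activity
#'
#' A cell is active when it shows at least one detected event. Frequency is
#' the mean over active cells of events per minute; duration is the mean
#' event duration over all events.
#'
#' @param events data.frame with a \code{cell} column as returned by the
#'   \code{CaTraceSet} method of \code{\link{detectCaEvents}}.
#' @param nCells total number of cells (> 0).
#' @param duration trace duration, s.
#' @return list with \code{pctActive} (percent of cells), \code{freq}
#'   (oscillations/min over active cells, NA if none), \code{meanDuration}
#'   (s, NA if no events), \code{nActive} and \code{nCells}.
#' @examples
#' ev <- data.frame(cell = rep(1, 12), begin = 1:12, end = 2:13,
#'                  duration = 1)
#' caMetrics(ev, nCells = 1, duration = 120)$freq  # 6 osc/min
#' @export
caMetrics <- function(events, nCells, duration) {
  if (nCells < 1) stop("nCells must be >= 1")
  if (duration <= 0) stop("duration must be > 0")
  nActive <- length(unique(events$cell))
  perCell <- if (nActive) as.numeric(table(events$cell)) else numeric(0)
  list(pctActive = 100 * nActive / nCells,
       freq = if (nActive) mean(perCell / (duration / 60)) else NA_real_,
       meanDuration = if (nrow(events)) mean(events$duration) else NA_real_,
       nActive = nActive, nCells = nCells)
}
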