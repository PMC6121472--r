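# Functional connectivity from delayed-synchronous spikes: cross-correlation
# matrix, top-quantile edge selection, hub identification and hub overlap.

#' Delayed-synchrony cross-correlation matrix
#'
#' For every ordered electrode pair (i, j), counts the spikes on j that
#' have at least one spike on i inside the tolerance window
#' \code{[t_j - tau - delta/2, t_j - tau + delta/2]}, where
#' \code{tau = distance(i, j) / velocity} is the distance-proportional
#' axonal delay. Each postsynaptic spike is counted at most once, so
#' \code{C[i, j] = n_synchr / n_j} always lies in [0, 1]. Electrodes
#' without spikes carry no synchrony evidence: their rows and columns are
#' flagged undefined and stored as 0.
#'
#' @param raster a \linkS4class{SpikeRaster} with spikes on at least two
#'   electrodes.
#' @param geometry an \linkS4class{ElectrodeGeometry}.
#' @param params a \linkS4class{SynchronyParams}.
#' @return A \linkS4class{SynchronyMatrix}.
#' @export
synchronyMatrix <- function(raster, geometry = ElectrodeGeometry(),
                            params = SynchronyParams()) {
  nEl <- nElectrodes(raster)
  if (nEl != nElectrodes(geometry))
    stop("raster and geometry disagree on the number of electrodes")
  counts <- electrodeSpikeCounts(raster)
  if (sum(counts > 0L) < 2L)
    stop("synchrony requires spikes on at least two electrodes")
  dmat <- electrodeDistances(geometry)
  halfDelta <- params@delta / 2000  # ms -> s, half window
  times <- split(spikeTimes(raster),
                 factor(spikeElectrodes(raster), levels = seq_len(nEl)))
  C <- matrix(0, nEl, nEl)
  active <- which(counts > 0L)
  for (j in active) {
    tj <- times[[j]]
    for (i in active) {
      if (i == j) next
      ti <- times[[i]]
      tau <- dmat[i, j] * 1e-6 / params@velocity  # um -> m, s
      lo <- tj - tau - halfDelta
      hi <- tj - tau + halfDelta
      # spikes of j with >= 1 spike of i in the closed window [lo, hi]
      nSynchr <- sum(findInterval(hi, ti) -
                     findInterval(lo, ti, left.open = TRUE) >= 1L)
      C[i, j] <- nSynchr / counts[j]
    }
  }
  new("SynchronyMatrix", values = C, nSpikes = as.integer(counts),
      defined = counts > 0L, velocity = params@velocity,
      delta = params@delta)
}

# Incident-edge count per electrode (in + out degree over directed edges).
.edgeDegrees <- function(edges, nEl) {
  tabulate(c(edges$src, edges$dst), nbins = nEl)
}

#' Select the strongest synchrony connections as graph edges
#'
#' The edge threshold is the empirical \code{quantile} (0.95 by default) of
#' all defined off-diagonal synchrony values; entries strictly above it
#' become directed edges -- the largest 5\% of coefficients. Entries tied in
#' value are kept or dropped together, so the selection is deterministic
#' and order-independent. Hubs are identified with the default rule of
#' \code{\link{identifyHubs}}.
#'
#' @param sm a \linkS4class{SynchronyMatrix}.
#' @param quantile selection quantile (default 0.95).
#' @return A \linkS4class{SynchronyGraph}.
#' @export
selectEdges <- function(sm, quantile = 0.95) {
  stopifnot(is(sm, "SynchronyMatrix"), quantile > 0, quantile < 1)
  nEl <- nrow(sm@values)
  pool <- sm@defined & TRUE
  mask <- outer(pool, pool, "&")
  diag(mask) <- FALSE
  vals <- sm@values[mask]
  emptyGraph <- function(thr) new("SynchronyGraph",
    edges = data.frame(src = integer(0), dst = integer(0),
                       weight = numeric(0)),
    degrees = integer(nEl),
    hubs = data.frame(electrode = integer(0), degree = integer(0),
                      hubCoefficient = numeric(0)),
    threshold = thr, nElectrodes = as.integer(nEl))
  if (!length(vals)) return(emptyGraph(NA_real_))
  if (max(vals) == min(vals)) {
    warning("all synchrony values are equal; no edges selected")
    return(emptyGraph(max(vals)))
  }
  thr <- stats::quantile(vals, quantile, names = FALSE)
  sel <- which(mask & sm@values > thr, arr.ind = TRUE)
  edges <- data.frame(src = sel[, 1], dst = sel[, 2],
                      weight = sm@values[sel])
  edges <- edges[order(edges$src, edges$dst), , drop = FALSE]
  rownames(edges) <- NULL
  g <- new("SynchronyGraph", edges = edges,
           degrees = .edgeDegrees(edges, nEl),
           hubs = data.frame(electrode = integer(0), degree = integer(0),
                             hubCoefficient = numeric(0)),
           threshold = thr, nElectrodes = as.integer(nEl))
  g@hubs <- identifyHubs(g)
  g
}

#' Identify hub electrodes of a functional graph
#'
#' Hubs are the electrodes with the most functionally active connections.
#' With the default percentile rule an electrode is a hub when its
#' incident-edge degree strictly exceeds the 90th percentile of nonzero
#' degrees; alternatively an explicit minimal degree can be given. Each hub
#' reports its degree (connections per hub) and its hub coefficient, the
#' ratio of its incident-edge count to the total number of edges in the
#' graph.
#'
#' @param graph a \linkS4class{SynchronyGraph}.
#' @param hubMinDegree optional explicit threshold: electrodes with degree
#'   \code{>= hubMinDegree} are hubs.
#' @return data.frame with columns \code{electrode}, \code{degree},
#'   \code{hubCoefficient}, sorted by decreasing degree.
#' @export
identifyHubs <- function(graph, hubMinDegree = NULL) {
  stopifnot(is(graph, "SynchronyGraph"))
  deg <- graph@degrees
  nz <- deg[deg > 0L]
  empty <- data.frame(electrode = integer(0), degree = integer(0),
                      hubCoefficient = numeric(0))
  if (!length(nz)) return(empty)
  sel <- if (is.null(hubMinDegree)) {
    deg > stats::quantile(nz, 0.9, names = FALSE)
  } else {
    deg >= hubMinDegree
  }
  if (!any(sel)) return(empty)
  idx <- which(sel)
  out <- data.frame(electrode = idx, degree = deg[idx],
                    hubCoefficient = deg[idx] / nEdges(graph))
  out <- out[order(-out$degree, out$electrode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage overlap between two hub sets
#'
#' Jaccard overlap in percent: \code{100 * |a intersect b| / |a union b|}.
#' Used to quantify how stable the hub population is between recording
#' sessions (e.g. different days in vitro).
#'
#' @param hubsA,hubsB integer vectors of hub electrode indices (or data
#'   frames with an \code{electrode} column).
#' @return numeric percentage in [0, 100]; 0 with a warning when both sets
#'   are empty.
#' @examples
#' hubOverlap(c(1, 2, 3, 4), c(1, 2, 5, 6))  # 100 * 2/6 = 33.33
#' @export
hubOverlap <- function(hubsA, hubsB) {
  getIdx <- function(h) {
    if (is.data.frame(h)) h <- h$electrode
    unique(as.integer(h))
  }
  a <- getIdx(hubsA); b <- getIdx(hubsB)
  u <- union(a, b)
  if (!length(u)) {
    warning("both hub sets are empty; overlap defined as 0")
    return(0)
  }
  100 * length(intersect(a, b)) / length(u)
}

#' Export a synchrony graph to igraph
#'
#' @param graph a \linkS4class{SynchronyGraph}.
#' @return a directed \code{igraph} graph with edge attribute
#'   \code{weight}; all electrodes appear as vertices.
#' @export
asIgraph <- function(graph) {
  stopifnot(is(graph, "SynchronyGraph"))
  igraph::graph_from_data_frame(
    graphEdges(graph),
    directed = TRUE,
    vertices = data.frame(name = seq_len(nElectrodes(graph))))
}
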