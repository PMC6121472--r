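mkMatrix <- function(C, nSpikes = NULL) {
  n <- nrow(C)
  if (is.null(nSpikes)) nSpikes <- rep(10L, n)
  new("SynchronyMatrix", values = C, nSpikes = as.integer(nSpikes),
      defined = nSpikes > 0L, velocity = 0.4, delta = 2)
}

test_that("synchrony matrix equals the brute-force window scan exactly", {
  geom <- ElectrodeGeometry(3, 3)
  for (s in 1:20) {
    set.seed(100 + s)
    n <- sample(100:400, 1)
    r <- SpikeRaster(sample(9, n, TRUE), runif(n, 0, 20),
                     nElectrodes = 9, duration = 20)
    sm <- synchronyMatrix(r, geom, SynchronyParams())
    expect_identical(synchronyValues(sm), bruteSynchrony(r, geom))
  }
})

test_that("synchrony entries are bounded by 1 and vanish without coincidences", {
  geom <- ElectrodeGeometry(1, 2)
  r <- SpikeRaster(c(1, 2), c(1, 10), nElectrodes = 2, duration = 20)
  sm <- synchronyMatrix(r, geom, SynchronyParams())
  expect_true(all(synchronyValues(sm) == 0))
  # perfect transmission: every postsynaptic spike is matched
  conn <- PlantedConnectivity(data.frame(src = 1, dst = 2),
                              transmissionProb = 1, velocity = 0.4)
  r2 <- generateConnectedRaster(conn, geom, 30, sourceRate = 5, seed = 51)
  sm2 <- synchronyMatrix(r2, geom, SynchronyParams())
  expect_equal(synchronyValues(sm2)[1, 2], 1)
  expect_true(all(synchronyValues(sm2) <= 1))
})

test_that("single-electrode rasters are rejected", {
  r <- SpikeRaster(rep(1, 5), 1:5, nElectrodes = 64, duration = 10)
  expect_error(synchronyMatrix(r, ElectrodeGeometry()), "two electrodes")
})

test_that("edge selection keeps exactly the strongest entries", {
  C <- matrix(0, 64, 64)
  picks <- cbind(2:11, 12:21)
  C[picks] <- 1
  g <- selectEdges(mkMatrix(C), 0.95)
  expect_equal(nEdges(g), 10)
  expect_equal(unname(as.matrix(graphEdges(g)[, c("src", "dst")])),
               unname(picks[order(picks[, 1]), ]))
  expect_warning(g0 <- selectEdges(mkMatrix(matrix(0, 64, 64))), "equal")
  expect_equal(nEdges(g0), 0)
  expect_equal(nrow(hubTable(g0)), 0)
})

test_that("the top-5% rule selects about 5% of a continuous matrix", {
  set.seed(52)
  C <- matrix(runif(64 * 64), 64, 64)
  diag(C) <- 0
  sm <- mkMatrix(C)
  g <- selectEdges(sm, 0.95)
  # oracle: sort the 4032 off-diagonal values and count above the
  # 95th percentile
  vals <- C[row(C) != col(C)]
  expect_equal(nEdges(g), sum(vals > quantile(vals, 0.95)))
  expect_lt(abs(nEdges(g) - 202), 3)
})

test_that("hub identification: star centre is the unique hub with coefficient 1", {
  C <- matrix(0, 64, 64)
  C[1, 2:11] <- 0.9
  g <- selectEdges(mkMatrix(C), 0.95)
  expect_equal(nEdges(g), 10)
  hubs <- hubTable(g)
  expect_equal(hubs$electrode, 1)
  expect_equal(hubs$degree, 10)
  expect_equal(hubs$hubCoefficient, 1.0)
})

test_that("hub identification: a degree-regular ring has no hubs", {
  C <- matrix(0, 64, 64)
  for (i in 1:10) C[i, i %% 10 + 1] <- 0.9
  g <- selectEdges(mkMatrix(C), 0.95)
  expect_equal(nEdges(g), 10)
  expect_equal(nrow(hubTable(g)), 0)  # all nonzero degrees equal 2
})

test_that("hub coefficients sum to 2 whenever edges exist", {
  set.seed(53)
  C <- matrix(runif(64 * 64), 64, 64)
  diag(C) <- 0
  g <- selectEdges(mkMatrix(C), 0.95)
  expect_equal(sum(electrodeDegrees(g)) / nEdges(g), 2)
})

test_that("hub overlap is the Jaccard percentage", {
  expect_equal(hubOverlap(c(3, 5, 9), c(3, 5, 9)), 100)
  expect_equal(hubOverlap(c(1, 2), c(3, 4)), 0)
  expect_equal(hubOverlap(c(1, 2, 3, 4), c(1, 2, 5, 6)), 100 * 2 / 6)
  expect_warning(o <- hubOverlap(integer(0), integer(0)), "empty")
  expect_equal(o, 0)
})

test_that("planted hub networks are recovered by top-5% selection", {
  geom <- ElectrodeGeometry()
  conn <- plantedHubConnectivity(geom, nHubs = 4, transmissionProb = 0.9)
  expect_equal(nrow(conn@edges), 16)
  r <- generateConnectedRaster(conn, geom, duration = 150, sourceRate = 2,
                               seed = 54)
  sm <- synchronyMatrix(r, geom, SynchronyParams())
  g <- selectEdges(sm, 0.95)
  planted <- paste(conn@edges$src, conn@edges$dst)
  found <- paste(graphEdges(g)$src, graphEdges(g)$dst)
  jac <- length(intersect(planted, found)) /
    length(union(planted, found))
  expect_gte(jac, 0.8)
  hubs <- identifyHubs(g, hubMinDegree = 4)
  planted <- unique(conn@edges$src)
  expect_true(all(planted %in% hubs$electrode))
  # the planted sources are the four best-connected electrodes
  expect_setequal(hubs$electrode[1:4], planted)
})

test_that("planted structure is recovered identically under velocity rescaling", {
  # regenerating the delays with a doubled velocity and analysing with the
  # matching parameter leaves the planted synchrony entries saturated and
  # the selected edge set unchanged
  geom <- ElectrodeGeometry(2, 4)
  edges <- data.frame(src = c(1, 5), dst = c(4, 8))
  strong <- list()
  for (v in c(0.4, 0.8)) {
    conn <- PlantedConnectivity(edges, transmissionProb = 1, velocity = v)
    r <- generateConnectedRaster(conn, geom, 30, sourceRate = 4, seed = 55)
    sm <- synchronyMatrix(r, geom, SynchronyParams(velocity = v))
    expect_equal(synchronyValues(sm)[1, 4], 1)
    expect_equal(synchronyValues(sm)[5, 8], 1)
    strong[[as.character(v)]] <- which(synchronyValues(sm) >= 0.5)
  }
  expect_identical(strong[["0.4"]], strong[["0.8"]])
})
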