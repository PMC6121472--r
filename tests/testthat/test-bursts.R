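emptyRaster <- function(duration = 600, nEl = 64) {
  SpikeRaster(integer(0), numeric(0), nElectrodes = nEl,
              duration = duration)
}

test_that("TSR of an empty raster is all-zero with the right bin count", {
  tsr <- computeTSR(emptyRaster(600), 50)
  expect_equal(length(tsr@counts), 12000)
  expect_true(all(tsr@counts == 0))
  expect_error(computeTSR(emptyRaster(), 0), "binWidth")
})

test_that("TSR bins are half-open and conserve the total spike count", {
  r <- volleyRaster(rep(1:5, 2), rep(0.01, 10), duration = 1)
  tsr <- computeTSR(r, 50)
  expect_equal(tsr@counts[1], 10)
  expect_true(all(tsr@counts[-1] == 0))
  expect_equal(tsr@activeElectrodes[1], 5)
  set.seed(41)
  r2 <- volleyRaster(sample(64, 1e4, TRUE), runif(1e4, 0, 600),
                     duration = 600)
  expect_equal(sum(computeTSR(r2, 50)@counts), 1e4)
})

test_that("a flat TSR yields no bursts", {
  bursts <- detectBursts(computeTSR(emptyRaster(10), 50), emptyRaster(10))
  expect_equal(nBursts(bursts), 0)
})

test_that("a volley on fewer than minElectrodes electrodes is not a burst", {
  mk <- function(nEl) {
    el <- rep(seq_len(nEl), each = 20)
    tm <- runif(20 * nEl, 1.0, 1.1)
    volleyRaster(el, tm, duration = 10)
  }
  set.seed(42)
  r3 <- mk(3)
  expect_equal(nBursts(detectBursts(computeTSR(r3, 50), r3)), 0)
  r4 <- mk(4)
  expect_equal(nBursts(detectBursts(computeTSR(r4, 50), r4)), 1)
})

test_that("burst boundaries refine to the first and last spike of the run", {
  tm <- c(1.002, 1.010, 1.020, 1.030, 1.040, 1.062)
  el <- c(1, 2, 3, 4, 1, 2)
  r <- volleyRaster(el, tm, duration = 10)
  bursts <- detectBursts(computeTSR(r, 50), r)
  expect_equal(nBursts(bursts), 1)
  bt <- burstTable(bursts)
  expect_equal(bt$start, 1.002)
  expect_equal(bt$end, 1.062)
  expect_equal(bt$nSpikes, 6)
  lat <- burstLatencies(bursts)[[1]]
  expect_equal(unname(lat[c("1", "2", "3", "4")]),
               c(0, 8, 18, 28))
})

test_that("planted burst durations are recovered within 10%", {
  gen <- generateBurstRaster(ElectrodeGeometry(), 60, burstRate = 60,
                             burstDuration = c(100, 400),
                             backgroundRate = 0.2, seed = 43)
  bursts <- detectBursts(computeTSR(gen$raster, 50), gen$raster)
  err <- burstDurationErrors(gen$truth$bursts, bursts)
  expect_lt(mean(is.na(err)), 0.05)   # nearly all bursts found
  expect_lte(median(err, na.rm = TRUE), 0.10)
})

test_that("lowering the threshold coefficient does not lose bursts", {
  # silent gaps between bursts: lowering the threshold can then only add
  # or extend suprathreshold runs, never merge them
  gen <- generateBurstRaster(ElectrodeGeometry(), 40, burstRate = 30,
                             burstDuration = c(100, 300),
                             backgroundRate = 0, seed = 44)
  tsr <- computeTSR(gen$raster, 50)
  n <- vapply(c(0.5, 0.2, 0.1, 0.05), function(coef) {
    nBursts(detectBursts(tsr, gen$raster, BurstDetectionParams(coef)))
  }, numeric(1))
  expect_true(all(diff(n) >= 0))
})

test_that("sparse Poisson background rarely produces false bursts", {
  gen <- generateBurstRaster(ElectrodeGeometry(), 600, burstRate = 0,
                             backgroundRate = 0.1, seed = 45)
  bursts <- detectBursts(computeTSR(gen$raster, 50), gen$raster)
  expect_lt(nBursts(bursts) / 10, 1)   # < 1 false burst per minute
})

test_that("burst metrics follow their definitions", {
  mkSet <- function(n, spikes, duration) {
    new("NetworkBurstSet",
        bursts = data.frame(start = seq_len(n), end = seq_len(n) + 0.1,
                            duration = rep(0.1, n), nSpikes = spikes),
        latencies = rep(list(c(`1` = 0)), n), duration = duration,
        threshold = 1, binWidth = 50)
  }
  m <- burstMetrics(mkSet(93, rep(100, 93), 300))
  expect_equal(m$burstsPer10min, 186)
  expect_equal(burstMetrics(mkSet(2, c(100, 200), 600))$meanSpikesPerBurst,
               150)
  empty <- detectBursts(computeTSR(emptyRaster(600), 50), emptyRaster(600))
  m0 <- burstMetrics(empty)
  expect_equal(m0$nBursts, 0)
  expect_equal(m0$burstsPer10min, 0)
  expect_true(is.na(m0$meanSpikesPerBurst))
})

test_that("activation pattern maps median first-spike latencies onto the grid", {
  set1 <- new("NetworkBurstSet",
              bursts = data.frame(start = 1, end = 1.2, duration = 0.2,
                                  nSpikes = 10),
              latencies = list(c(`5` = 7, `1` = 0)), duration = 10,
              threshold = 1, binWidth = 50)
  map <- activationPattern(set1, ElectrodeGeometry())
  expect_equal(map[1, 5], 7)   # electrode 5 sits at row 1, col 5
  expect_equal(map[1, 1], 0)
  expect_true(is.na(map[8, 8]))
  expect_error(activationPattern(detectBursts(
    computeTSR(emptyRaster(10), 50), emptyRaster(10))), "burst")
})

test_that("corner-origin bursts reproduce the distance/velocity activation map exactly", {
  geom <- ElectrodeGeometry()
  gen <- generateBurstRaster(geom, 60, burstRate = 20,
                             burstDuration = c(300, 300),
                             nElectrodesPerBurst = 64, backgroundRate = 0,
                             velocity = 0.4, originPolicy = "corner",
                             jitterSd = 0, seed = 46)
  bursts <- detectBursts(computeTSR(gen$raster, 50), gen$raster)
  expect_gt(nBursts(bursts), 5)
  map <- activationPattern(bursts, geom)
  d <- electrodeDistances(geom)[1, ]
  expected <- matrix(d / (0.4 * 1000), 8, 8, byrow = TRUE)
  expect_equal(map, expected, tolerance = 1e-9)
})

test_that("jittered activation maps stay within 1 ms of the planted delays", {
  geom <- ElectrodeGeometry()
  gen <- generateBurstRaster(geom, 90, burstRate = 20,
                             burstDuration = c(300, 300),
                             nElectrodesPerBurst = 64, backgroundRate = 0,
                             originPolicy = "corner", jitterSd = 0.5,
                             seed = 47)
  bursts <- detectBursts(computeTSR(gen$raster, 50), gen$raster)
  map <- activationPattern(bursts, geom)
  expected <- matrix(electrodeDistances(geom)[1, ] / (0.4 * 1000), 8, 8,
                     byrow = TRUE)
  expect_lt(mean(abs(map - expected)), 1)
})
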