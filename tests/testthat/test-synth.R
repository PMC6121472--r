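geomSmall <- ElectrodeGeometry(2, 2)

test_that("raw generator: zero noise and empty schedule give an all-zero recording", {
  rec <- generateRawRecording(geomSmall, duration = 1, noiseSd = 0)
  expect_true(all(signalMatrix(rec) == 0))
  expect_equal(ncol(signalMatrix(rec)), 20000)
})

test_that("raw generator places a biphasic spike with the stated peak amplitude", {
  sched <- data.frame(electrode = 1, time = 0.5, amplitude = 30)
  rec <- generateRawRecording(geomSmall, duration = 1, noiseSd = 0,
                              spikeSchedule = sched)
  sig <- signalMatrix(rec)
  expect_equal(max(abs(sig[1, ])), 30)
  expect_equal(which.max(abs(sig[1, ])), round(0.5 * 20000) + 1)
  expect_lt(min(sig[1, ]), 0)   # negative trough first
  expect_gt(max(sig[1, ]), 0)   # positive overshoot
  expect_true(all(sig[2:4, ] == 0))
})

test_that("raw generator rejects out-of-range schedules", {
  expect_error(generateRawRecording(
    geomSmall, 1, 0, data.frame(electrode = 1, time = 1.5, amplitude = 30)),
    "time")
  expect_error(generateRawRecording(
    geomSmall, 1, 0, data.frame(electrode = 1, time = 0.5, amplitude = -30)),
    "amplitude")
})

test_that("raw generator noise matches the requested standard deviation", {
  rec <- generateRawRecording(geomSmall, duration = 10, noiseSd = 5,
                              seed = 11)
  sds <- apply(signalMatrix(rec), 1, sd)
  expect_true(all(abs(sds - 5) / 5 < 0.02))
})

test_that("generators are bit-identical under a fixed seed", {
  g <- ElectrodeGeometry()
  a <- generateBurstRaster(g, 20, 30, c(100, 300), seed = 7)
  b <- generateBurstRaster(g, 20, 30, c(100, 300), seed = 7)
  expect_identical(spikeTimes(a$raster), spikeTimes(b$raster))
  expect_identical(a$truth, b$truth)
  ca1 <- generateCaTraces(5, 0.8, 6.9, 6.23, duration = 60, seed = 3)
  ca2 <- generateCaTraces(5, 0.8, 6.9, 6.23, duration = 60, seed = 3)
  expect_identical(traceMatrix(ca1$traces), traceMatrix(ca2$traces))
})

test_that("burst raster: silent configuration yields an empty raster and truth", {
  out <- generateBurstRaster(ElectrodeGeometry(), 10, burstRate = 0,
                             backgroundRate = 0, seed = 1)
  expect_equal(nSpikes(out$raster), 0)
  expect_equal(nrow(out$truth$bursts), 0)
})

test_that("burst raster: planted burst count falls in the Poisson 99% interval", {
  out <- generateBurstRaster(ElectrodeGeometry(), 60, burstRate = 60,
                             burstDuration = c(100, 300),
                             backgroundRate = 0, seed = 5)
  n <- nrow(out$truth$bursts)
  expect_gte(n, qpois(0.005, 60))
  expect_lte(n, qpois(0.995, 60))
})

test_that("burst raster: every planted first spike appears in the raster", {
  out <- generateBurstRaster(ElectrodeGeometry(), 30, burstRate = 30,
                             burstDuration = c(100, 300),
                             backgroundRate = 0, seed = 9)
  tm <- spikeTimes(out$raster)
  el <- spikeElectrodes(out$raster)
  for (b in seq_len(nrow(out$truth$bursts))) {
    t0 <- out$truth$bursts$start[b]
    lat <- out$truth$firstSpike[[b]]
    for (k in seq_along(lat)) {
      e <- as.integer(names(lat)[k])
      expect_true(any(el == e & abs(tm - (t0 + lat[k] / 1000)) < 1e-9))
    }
  }
})

test_that("burst propagation delay is distance/velocity exactly without jitter", {
  out <- generateBurstRaster(ElectrodeGeometry(), 30, burstRate = 10,
                             burstDuration = c(200, 200),
                             nElectrodesPerBurst = 2, backgroundRate = 0,
                             velocity = 0.4, originPolicy = "corner",
                             jitterSd = 0, seed = 2)
  lat <- out$truth$firstSpike[[1]]
  # corner origin (electrode 1) and its nearest neighbour, 150 um away
  expect_equal(unname(diff(sort(lat))), 150 / (0.4 * 1000))
})

test_that("background rate calibration converges at long duration", {
  out <- generateBurstRaster(ElectrodeGeometry(), 600, burstRate = 0,
                             backgroundRate = 2, seed = 13)
  rates <- electrodeSpikeCounts(out$raster) / 600
  expect_lt(abs(mean(rates) - 2) / 2, 0.05)
})

test_that("connected raster copies every source spike at the exact delay when p = 1", {
  conn <- PlantedConnectivity(data.frame(src = 1, dst = 2),
                              transmissionProb = 1, velocity = 0.4)
  r <- generateConnectedRaster(conn, geomSmall, duration = 20,
                               sourceRate = 5, seed = 4)
  delay <- 150 * 1e-6 / 0.4
  tSrc <- spikeTimes(r)[spikeElectrodes(r) == 1]
  tDst <- spikeTimes(r)[spikeElectrodes(r) == 2]
  expected <- tSrc + delay
  expect_equal(tDst, expected[expected < 20])
})

test_that("connected raster: p = 0 leaves the postsynaptic electrode silent", {
  conn <- PlantedConnectivity(data.frame(src = 1, dst = 2),
                              transmissionProb = 0)
  r <- generateConnectedRaster(conn, geomSmall, 20, sourceRate = 5,
                               seed = 4)
  expect_equal(sum(spikeElectrodes(r) == 2), 0)
})

test_that("connected raster transmission count falls in the binomial 99% interval", {
  conn <- PlantedConnectivity(data.frame(src = 1, dst = 2),
                              transmissionProb = 0.5)
  r <- generateConnectedRaster(conn, geomSmall, duration = 100,
                               sourceRate = 100, seed = 6)
  nSrc <- sum(spikeElectrodes(r) == 1)
  nDst <- sum(spikeElectrodes(r) == 2)
  expect_gte(nDst, qbinom(0.005, nSrc, 0.5))
  expect_lte(nDst, qbinom(0.995, nSrc, 0.5))
})

test_that("planted self-edges and bad probabilities are rejected", {
  expect_error(PlantedConnectivity(data.frame(src = 1, dst = 1)), "self")
  expect_error(PlantedConnectivity(data.frame(src = 1, dst = 2),
                                   transmissionProb = 1.5), "transmissionProb")
})

test_that("calcium generator honours the active fraction exactly", {
  out <- generateCaTraces(100, 0.97, rate = 2, meanDuration = 6,
                          duration = 30, seed = 8)
  expect_equal(length(out$truth$activeCells), 97)
  none <- generateCaTraces(10, 0, rate = 6.9, meanDuration = 6.23,
                           duration = 30, seed = 8)
  expect_equal(nrow(none$truth$events), 0)
})

test_that("a planted calcium event spans duration * frameRate frames above baseline", {
  out <- generateCaTraces(1, 1, rate = 4, meanDuration = 6,
                          amplitude = 50, noiseSd = 0, duration = 120,
                          seed = 15)
  expect_gt(nrow(out$truth$events), 0)
  ev <- out$truth$events[1, ]
  tr <- traceMatrix(out$traces)[, 1]
  # frames strictly above baseline within the first event's window
  tt <- (seq_along(tr) - 0.5) / 4
  frames <- sum(tr > 20 + 1e-6 & tt > ev$begin - 1 & tt < ev$end + 1)
  expect_lte(abs(frames - (ev$end - ev$begin) * 4), 1.5)
})

test_that("calcium ground-truth event statistics match the requested presets", {
  out <- generateCaTraces(20, 1, rate = 6.9, meanDuration = 6.23,
                          duration = 300, seed = 21)
  ev <- out$truth$events
  perCell <- as.numeric(table(factor(ev$cell, levels = 1:20)))
  empRate <- mean(perCell) / (300 / 60)
  expect_lt(abs(empRate - 6.9) / 6.9, 0.10)
  expect_lt(abs(mean(ev$end - ev$begin) - 6.23) / 6.23, 0.05)
  # events never overlap within a cell
  for (c in unique(ev$cell)) {
    e <- ev[ev$cell == c, ]
    if (nrow(e) > 1)
      expect_true(all(e$begin[-1] > e$end[-nrow(e)]))
  }
})

test_that("calcium generator warns when events would clip at 255", {
  expect_warning(generateCaTraces(2, 1, 2, 6, amplitude = 240,
                                  duration = 30, seed = 1), "clip")
})
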