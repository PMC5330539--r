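test_that("the bin-occupancy definition forces sizes, durations, waits", {
  # occupancy per 1-ms bin: [0, 2, 3, 0, 1, 0], all spikes distinct neurons
  r <- rasterFromSpikes(neuron = 1:6,
                        time = c(1.2, 1.7, 2.1, 2.5, 2.9, 4.4),
                        n_neurons = 6, duration = 6)
  av <- extractAvalanches(r, delta_t = 1)
  expect_identical(avalancheSizes(av), c(5L, 1L))
  expect_identical(avalancheDurations(av), c(2L, 1L))
  expect_identical(waitingTimes(av), 1)
})

test_that("a silent raster yields an empty set with a warning", {
  r <- spikeData(list(numeric(), numeric()), c("E", "E"), 100)
  expect_warning(av <- extractAvalanches(r, delta_t = 1), "no spikes")
  expect_identical(length(avalancheSizes(av)), 0L)
})

test_that("distinct-neuron and spike-count sizes differ for bursts", {
  r <- rasterFromSpikes(neuron = c(1, 1), time = c(1.2, 1.8),
                        n_neurons = 2, duration = 4)
  expect_identical(avalancheSizes(extractAvalanches(r, 1, size = "neurons")),
                   1L)
  expect_identical(avalancheSizes(extractAvalanches(r, 1, size = "spikes")),
                   2L)
})

test_that("the time axis partitions into runs, gaps and flanks exactly", {
  po <- generateSurrogate("poisson", n_neurons = 20, rate = 15,
                          duration = 30, seed = 9)
  av <- extractAvalanches(po, delta_t = 1)
  dur_bins <- sum(avalancheDurations(av))
  gap_bins <- sum(waitingTimes(av)) / av@binWidth
  lead <- av@startBin[1]
  k <- length(avalancheSizes(av))
  last_end <- av@startBin[k] + avalancheDurations(av)[k] - 1L
  trail <- av@nBins - 1L - last_end
  expect_identical(dur_bins + as.integer(gap_bins) + lead + trail,
                   av@nBins)
  # no spike lost: spike-count sizes account for every binned spike
  total <- sum(lengths(spikeTimes(po)))
  expect_identical(sum(av@sizesSpikes), as.integer(total))
})

test_that("critical-state distance is stable across fine bin widths", {
  s <- referenceRaster(4, 10)
  d1 <- plDistance(fitPowerLaw(extractAvalanches(s, delta_t = 0.1)))
  d2 <- plDistance(fitPowerLaw(extractAvalanches(s, delta_t = 0.2)))
  expect_lt(max(d1, d2) / min(d1, d2), 2)
})
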